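#' Clustering parameters for molecule counting
#'
#' Defaults mirror the assay's counting step: tags within edit distance 2 are
#' merged; the 30-bp tag carries 6 fixed and 24 random bases. Distance is
#' computed over the full tag; because filtered tags agree at every fixed
#' position, this equals the distance over the random bases alone.
#'
#' @param distance Maximum distance for a tag to join a cluster (default 2).
#' @param fixed_base_number,random_base_number Tag composition; their sum
#'   must equal the tag length of the data being clustered.
#' @param metric `"hamming"` (default; tags are fixed-length) or
#'   `"levenshtein"` (via [utils::adist()]).
#' @param linkage `"greedy"` (default; abundance-ordered representative
#'   clustering) or `"single"` (transitive single-linkage components, for
#'   sensitivity analysis).
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(distance = 2L, fixed_base_number = 6L,
                           random_base_number = 24L,
                           metric = c("hamming", "levenshtein"),
                           linkage = c("greedy", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  stopifnot(distance >= 0L, fixed_base_number >= 0L, random_base_number >= 0L)
  structure(list(distance = as.integer(distance),
                 fixed_base_number = as.integer(fixed_base_number),
                 random_base_number = as.integer(random_base_number),
                 metric = metric, linkage = linkage),
            class = "cluster_params")
}

# distinct tags with read counts, in greedy processing order:
# read count descending, then tag ascending (deterministic tie-break)
.tag_census <- function(tags) {
  if (length(tags) == 0L)
    return(data.frame(tag = character(0), reads = integer(0),
                      stringsAsFactors = FALSE))
  if (length(unique(nchar(tags))) != 1L)
    stop("counting tags have inconsistent lengths")
  tab <- table(tags)
  df <- data.frame(tag = names(tab), reads = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$reads, df$tag), , drop = FALSE]
}

.dist_fun <- function(params) {
  if (params$metric == "hamming") {
    function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  } else {
    function(a, b) as.integer(utils::adist(a, b))
  }
}

# order clusters by total reads desc then representative asc, renumber,
# order members within cluster by reads desc then tag asc
.finalize_clusters <- function(census, assignment, representative) {
  if (nrow(census) == 0L)
    return(data.frame(cluster = integer(0), representative = character(0),
                      tag = character(0), reads = integer(0),
                      stringsAsFactors = FALSE))
  totals <- tapply(census$reads, assignment, sum)
  reps <- representative[as.integer(names(totals))]
  ord <- order(-as.integer(totals), reps)
  renum <- integer(length(totals))
  renum[as.integer(names(totals))[ord]] <- seq_along(ord)
  out <- data.frame(cluster = renum[assignment],
                    representative = representative[assignment],
                    tag = census$tag, reads = census$reads,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$reads, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster counting tags into molecules
#'
#' Greedy abundance-ordered clustering: distinct tags are visited in order of
#' decreasing read count (ties broken lexicographically); each tag joins the
#' earliest-seeded cluster whose representative lies within
#' `params$distance`, otherwise it seeds a new cluster whose representative
#' it becomes. The result is deterministic and independent of input read
#' order. Each resulting cluster is one inferred molecule.
#'
#' With `linkage = "single"`, tags are instead merged transitively whenever
#' any pair is within distance; the most abundant member represents each
#' component.
#'
#' @param tags Character vector: one element per read (a multiset of tags;
#'   all the same length, all expected to have passed the fixed-base filter).
#' @param params A [cluster_params()].
#' @return `data.frame` with one row per distinct tag: `cluster` (1-based,
#'   ordered by total reads descending then representative), `representative`,
#'   `tag`, `reads`. The number of molecules is `max(cluster)` (0 if empty).
#' @export
cluster_tags <- function(tags, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  census <- .tag_census(tags)
  k <- nrow(census)
  if (k == 0L) return(.finalize_clusters(census, integer(0), character(0)))
  if (params$linkage == "single")
    return(.single_linkage(census, params))
  assignment <- integer(k)
  rep_idx <- integer(0)            # census rows that seed clusters, in order
  if (params$metric == "hamming") {
    mat <- .char_matrix(census$tag)
    for (i in seq_len(k)) {
      hit <- 0L
      if (length(rep_idx)) {
        d <- colSums(mat[, rep_idx, drop = FALSE] != mat[, i])
        w <- which(d <= params$distance)
        if (length(w)) hit <- w[1L]
      }
      if (hit > 0L) assignment[i] <- hit
      else { rep_idx <- c(rep_idx, i); assignment[i] <- length(rep_idx) }
    }
  } else {
    for (i in seq_len(k)) {
      hit <- 0L
      if (length(rep_idx)) {
        d <- utils::adist(census$tag[rep_idx], census$tag[i])
        w <- which(d <= params$distance)
        if (length(w)) hit <- w[1L]
      }
      if (hit > 0L) assignment[i] <- hit
      else { rep_idx <- c(rep_idx, i); assignment[i] <- length(rep_idx) }
    }
  }
  # representative per cluster = its seeding tag
  rep_of_cluster <- census$tag[rep_idx]
  .finalize_clusters(census, assignment, rep_of_cluster)
}

.single_linkage <- function(census, params) {
  k <- nrow(census)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  mat <- if (params$metric == "hamming") .char_matrix(census$tag) else NULL
  for (i in seq_len(k - 1L)) {
    d <- if (!is.null(mat)) colSums(mat[, (i + 1L):k, drop = FALSE] != mat[, i])
         else as.integer(utils::adist(census$tag[(i + 1L):k], census$tag[i]))
    for (j in which(d <= params$distance)) {
      a <- find(i); b <- find(i + j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  # relabel components to dense 1..m; census is abundance-sorted, so the
  # first member of each component is its most abundant tag
  labels <- match(comp, unique(comp))
  rep_tags <- census$tag[match(unique(comp), comp)]
  .finalize_clusters(census, labels, rep_tags)
}

#' Brute-force reference clusterer
#'
#' Literal O(n^2) re-implementation of the greedy abundance-ordered rule with
#' an explicit pairwise distance matrix, used as an independent oracle in
#' tests. Must agree exactly with [cluster_tags()].
#'
#' @inheritParams cluster_tags
#' @return Same structure as [cluster_tags()].
#' @export
brute_force_cluster <- function(tags, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  census <- .tag_census(tags)
  k <- nrow(census)
  if (k > 2000L) stop("brute_force_cluster is limited to 2000 distinct tags")
  if (k == 0L) return(.finalize_clusters(census, integer(0), character(0)))
  dist_fn <- .dist_fun(params)
  dm <- matrix(0L, k, k)
  for (i in seq_len(k))
    for (j in seq_len(k))
      dm[i, j] <- dist_fn(census$tag[i], census$tag[j])
  assignment <- integer(k)
  reps <- integer(0)
  for (i in seq_len(k)) {
    joined <- FALSE
    for (ci in seq_along(reps)) {
      if (dm[reps[ci], i] <= params$distance) {
        assignment[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  .finalize_clusters(census, assignment, census$tag[reps])
}

#' Count unique molecules per protein
#'
#' Groups passed-filter observations by protein, clusters each group's
#' counting tags, and reports per-protein read tallies and molecule counts.
#' Clustering is independent across proteins. Reads failing the fixed-base
#' filter are excluded from counting entirely; reads from `unused`-role
#' identifiers are tallied like any other protein and feed the noise floor.
#'
#' @param observations Observation `data.frame` from [demultiplex()].
#' @param schema The `barcode_schema` the observations were produced with.
#' @param params A [cluster_params()]; its `fixed_base_number +
#'   random_base_number` must equal the schema tag length.
#' @return An object of class `molecule_count_table`: a `data.frame` with one
#'   row per schema identifier (`protein`, `role`, `assigned_reads`,
#'   `filtered_reads`, `molecule_count`) and attributes `total_reads`,
#'   `unassigned_reads` and `clusters` (named list of per-protein cluster
#'   tables).
#' @export
count_molecules <- function(observations, schema, params = cluster_params()) {
  stopifnot(inherits(schema, "barcode_schema"),
            inherits(params, "cluster_params"))
  if (params$fixed_base_number + params$random_base_number != schema$tag_length)
    stop("fixed + random base number must equal the schema tag length")
  ids <- schema$identifiers
  assigned <- integer(nrow(ids))
  filtered <- integer(nrow(ids))
  molecules <- integer(nrow(ids))
  clusters <- stats::setNames(vector("list", nrow(ids)), ids$name)
  for (i in seq_len(nrow(ids))) {
    sel <- !is.na(observations$protein) & observations$protein == ids$name[i]
    assigned[i] <- sum(sel)
    keep <- sel & observations$passed_filter
    filtered[i] <- sum(keep)
    cl <- cluster_tags(observations$counting_tag[keep], params)
    clusters[[i]] <- cl
    molecules[i] <- if (nrow(cl)) max(cl$cluster) else 0L
  }
  out <- data.frame(protein = ids$name, role = ids$role,
                    assigned_reads = assigned, filtered_reads = filtered,
                    molecule_count = molecules, stringsAsFactors = FALSE)
  attr(out, "total_reads") <- nrow(observations)
  attr(out, "unassigned_reads") <- sum(is.na(observations$protein))
  attr(out, "clusters") <- clusters
  class(out) <- c("molecule_count_table", "data.frame")
  out
}

#' Serialize a molecule count table
#'
#' @param table A `molecule_count_table`.
#' @param path TSV path.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
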
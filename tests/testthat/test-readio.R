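test_that("FASTQ round-trips in order, plain and gzipped, including empty files", {
  reads <- data.frame(
    read_id = c("r1", "r2"),
    sequence = c("ACGTACGT", "TTTTACGT"),
    quality = c("IIIIIIII", "IIIIIIII"),
    stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  for (name in c("toy.fastq", "toy.fastq.gz")) {
    path <- file.path(dir, name)
    write_fastq(reads, path)
    expect_identical(read_fastq(path), reads)
  }
  empty <- file.path(dir, "empty.fastq")
  file.create(empty)
  expect_equal(nrow(read_fastq(empty)), 0L)
})

test_that("malformed FASTQ errors name the offending record", {
  dir <- withr::local_tempdir()
  trunc <- file.path(dir, "trunc.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), trunc)
  expect_error(read_fastq(trunc), "record 2")
  badhdr <- file.path(dir, "badhdr.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), badhdr)
  expect_error(read_fastq(badhdr), "record 2")
})

test_that("region extraction respects offsets and read-length boundaries", {
  sch <- toy_schema()
  r76 <- strrep("ACGT", 19)       # 76-mer
  expect_identical(extract_region(r76, sch), substr(r76, 1, 38))
  r38 <- substr(r76, 1, 38)
  expect_identical(extract_region(r38, sch), r38)
  expect_true(is.na(extract_region(substr(r76, 1, 37), sch)))

  off <- barcode_schema(sch$identifiers, sch$pattern, read_offset = 5L)
  expect_identical(extract_region(r76, off), substr(r76, 6, 43))
})

test_that("protein assignment matches brute force over all single substitutions", {
  ids <- protein_identifiers(c("AAAAAAAA", "CCCCAAAA", "AAAACCCC"),
                             c("p1", "p2", "p3"))
  sch <- barcode_schema(ids, min_id_distance = 3L)
  expect_equal(nrow(validate_schema(sch)), 0L)
  set.seed(1)
  tag <- random_counting_tag(sch$pattern, 1)
  for (k in 1:3) {
    idtag <- ids$tag[k]
    # exact match
    r <- assign_protein(paste0(idtag, tag), sch)
    expect_equal(r$protein, ids$name[k])
    expect_equal(r$id_mismatches, 0L)
    # all 8 x 3 single substitutions recover the same protein at distance 1
    for (pos in 1:8) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(idtag, pos, pos))) {
        mut <- idtag
        substr(mut, pos, pos) <- alt
        r <- assign_protein(paste0(mut, tag), sch)
        expect_equal(r$protein, ids$name[k])
        expect_equal(r$id_mismatches, 1L)
      }
    }
  }
  # two substitutions: beyond max_mismatch 1 -> unassigned
  r <- assign_protein(paste0("AATTAAAA", tag), sch)
  expect_true(is.na(r$protein))
})

test_that("ties at the minimum identifier distance are unassigned", {
  ids <- protein_identifiers(c("AAAAAAAA", "AACCAAAA"), c("p1", "p2"))
  sch <- barcode_schema(ids, min_id_distance = 2L)
  set.seed(2)
  tag <- random_counting_tag(sch$pattern, 1)
  # query at distance 1 from both identifiers
  r <- assign_protein(paste0("AACAAAAA", tag), sch)
  expect_true(is.na(r$protein))
})

test_that("max_mismatch = 0 equals exact dictionary lookup", {
  sch <- toy_schema()
  set.seed(3)
  regions <- paste0(
    sample(c(sch$identifiers$tag,
             replicate(5, paste(sample(c("A", "C", "G", "T"), 8,
                                       replace = TRUE), collapse = ""))),
           50, replace = TRUE),
    random_counting_tag(sch$pattern, 50))
  got <- assign_protein(regions, sch, max_mismatch = 0L)$protein
  oracle <- sch$identifiers$name[match(substr(regions, 1, 8),
                                       sch$identifiers$tag)]
  expect_identical(got, oracle)
})

test_that("fixed-base mismatches are counted and filter as specified", {
  sch <- toy_schema()
  id <- sch$identifiers$tag[1]
  set.seed(4)
  tag <- random_counting_tag(sch$pattern, 1)
  good <- check_fixed_bases(paste0(id, tag), sch)
  expect_equal(good$fixed_mismatches, 0L)
  expect_identical(good$counting_tag, tag)

  bad <- tag
  p <- sch$pattern$fixed_positions[3]
  substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                               sch$pattern$fixed_bases[3])[1]
  expect_equal(check_fixed_bases(paste0(id, bad), sch)$fixed_mismatches, 1L)

  obs <- demultiplex(
    data.frame(read_id = c("a", "b"),
               sequence = paste0(id, c(tag, bad), sch$arm3),
               stringsAsFactors = FALSE), sch)
  expect_identical(obs$passed_filter, c(TRUE, FALSE))
  expect_identical(obs$reason, c(NA_character_, "fixed_base"))
})

test_that("uniform random tags average 4.5 fixed-base mismatches", {
  # each of the 6 fixed positions mismatches with probability 3/4
  sch <- toy_schema()
  n <- 20000
  set.seed(5)
  tags <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  m <- mean(fixed_base_mismatches(tags, sch$pattern))
  se <- sqrt(6 * 0.75 * 0.25 / n)
  expect_lt(abs(m - 4.5), 3 * se + 1e-9)
})

test_that("demultiplexing is permutation-equivariant", {
  sch <- toy_schema()
  sim <- simulate_experiment(sim_config(
    sch, c(protein01 = 10, protein02 = 5), reads_out = 300,
    seq_error_rate = 0.01, unassigned_fraction = 0.05, seed = 6))
  obs <- demultiplex(sim$reads, sch)
  set.seed(7)
  perm <- sample(nrow(sim$reads))
  obs_perm <- demultiplex(sim$reads[perm, ], sch)
  rownames(obs_perm) <- NULL
  expect_identical(obs_perm, local({ x <- obs[perm, ]; rownames(x) <- NULL; x }))
})
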
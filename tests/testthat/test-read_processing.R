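test_that("quality trimming follows the 4-base window rule", {
  mk <- function(q) {
    tibble::tibble(read_id = "r", sequence = paste(rep("A", length(q)),
                                                   collapse = ""),
                   quality = intToUtf8(q + 33L))
  }
  # all high quality: unchanged
  r <- quality_trim(mk(rep(38, 80)))
  expect_equal(nchar(r$sequence), 80)
  # last 50 bases low: cut where the window mean first dips, computed by an
  # independent position-by-position oracle
  q <- c(rep(38, 50), rep(10, 50))
  oracle_cut <- function(q, thr = 25) {
    for (i in seq_along(q)) {
      win <- q[i:min(i + 3, length(q))]
      if (mean(win) < thr) return(i - 1L)
    }
    length(q)
  }
  r2 <- quality_trim(mk(q))
  expect_equal(nchar(r2$sequence), oracle_cut(q))
  expect_equal(nchar(r2$sequence), nchar(r2$quality))
  # random quality strings agree with the oracle
  set.seed(21)
  for (i in 1:20) {
    q <- sample(5:40, 60, replace = TRUE)
    expect_equal(nchar(quality_trim(mk(q))$sequence), oracle_cut(q))
  }
  # an all-low read becomes empty
  expect_equal(nchar(quality_trim(mk(rep(10, 30)))$sequence), 0)
})

test_that("length/ambiguity filter partitions exactly by the stated rules", {
  reads <- tibble::tibble(
    read_id = c("len149", "len150", "len151", "oneN", "cleanlong"),
    sequence = c(strrep("A", 149), strrep("A", 150), strrep("A", 151),
                 paste0(strrep("A", 150), "N", strrep("A", 149)),
                 strrep("ACGT", 80)),
    quality = NA_character_
  )
  fl <- filter_reads(reads)
  expect_setequal(fl$kept$read_id, c("len150", "len151", "cleanlong"))
  expect_equal(fl$discarded$reason[fl$discarded$read_id == "len149"],
               "length")
  expect_equal(fl$discarded$reason[fl$discarded$read_id == "oneN"],
               "ambiguous")
  expect_equal(nrow(fl$kept) + nrow(fl$discarded), nrow(reads))
})

test_that("filter conserves reads over random inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(0:50, 1)
    reads <- tibble::tibble(
      read_id = paste0("r", seq_len(n)),
      sequence = vapply(seq_len(n), function(j) {
        s <- random_dna(sample(100:300, 1))
        if (stats::runif(1) < 0.3) substr(s, 5, 5) <- "N"
        s
      }, character(1)),
      quality = NA_character_
    )
    fl <- filter_reads(reads)
    expect_equal(nrow(fl$kept) + nrow(fl$discarded), n)
    expect_setequal(c(fl$kept$read_id, fl$discarded$read_id), reads$read_id)
  }
})

test_that("dereplication counts equal a dictionary-count oracle", {
  reads <- tibble::tibble(read_id = paste0("r", 1:5),
                          sequence = rep("ACGTACGT", 5))
  u <- dereplicate(reads)
  expect_equal(nrow(u), 1)
  expect_equal(u$count, 5L)
  expect_equal(u$representative_id, "r1")
  set.seed(17)
  pool <- vapply(1:8, function(i) random_dna(30), "")
  reads2 <- tibble::tibble(read_id = paste0("r", 1:200),
                           sequence = sample(pool, 200, replace = TRUE))
  u2 <- dereplicate(reads2)
  want <- table(reads2$sequence)
  expect_equal(sum(u2$count), 200L)
  expect_equal(stats::setNames(u2$count, u2$sequence)[names(want)],
               stats::setNames(as.integer(want), names(want)))
  # ordering: count desc then sequence asc
  expect_true(all(diff(u2$count) <= 0))
})

test_that("identity model agrees with Biostrings overlap alignment", {
  set.seed(77)
  suppressWarnings(requireNamespace("Biostrings"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  for (i in 1:25) {
    a <- random_dna(150)
    b <- mutate_dna(a, 0.05)
    if (stats::runif(1) < 0.5) b <- substr(b, 1, sample(100:150, 1))
    got <- seq_identity(b, a, band = 200)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(b), Biostrings::DNAString(a),
      type = "overlap", gapOpening = 0, gapExtension = 5,
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3)
    )
    want <- Biostrings::pid(aln, "PID1") / 100
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("tiny clusterings are exact", {
  u <- dereplicate(tibble::tibble(read_id = c("a", "b"),
                                  sequence = rep(strrep("ACGT", 50), 2)))
  otus <- cluster_otus(u)
  expect_equal(nrow(otus), 1)
  expect_equal(otus$size, 2L)
  # two sequences at ~90% identity split at a 97% threshold
  set.seed(55)
  s1 <- random_dna(200)
  s2 <- mutate_dna(s1, 0.1)
  u2 <- dereplicate(tibble::tibble(read_id = c("a", "b"),
                                   sequence = c(s1, s2)))
  expect_equal(nrow(cluster_otus(u2)), 2)
})

test_that("greedy clustering equals the all-pairs distance-matrix oracle", {
  set.seed(202)
  params <- clustering_params()
  for (rep in 1:10) {
    parents <- vapply(1:6, function(i) random_dna(180), "")
    seqs <- vapply(1:30, function(i) {
      p <- sample(parents, 1)
      s <- mutate_dna(p, sample(c(0.005, 0.01, 0.05), 1))
      substr(s, 1, sample(120:180, 1))
    }, "")
    u <- dereplicate(tibble::tibble(read_id = paste0("r", 1:60),
                                    sequence = sample(rep(seqs, 2))))
    got <- cluster_otus(u, params)
    want <- oracle_greedy_clusters(u, params)
    expect_equal(length(want), nrow(got))
    got_sets <- lapply(got$member_ids, sort)
    want_sets <- lapply(want, function(ss) {
      sort(unlist(u$read_ids[u$sequence %in% ss]))
    })
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})

test_that("clustering is stable under read-order permutation", {
  fx <- get_fixture()
  comm <- build_mock_community(fx$fix$panel, 10, "offt01_syn")
  reads <- simulate_reads(comm, fx$amplicons,
                          read_sim_params(total_reads = 400, seed = 14))
  key <- function(otus) {
    sort(vapply(otus$member_ids, function(ids) paste(sort(ids),
                                                     collapse = ","), ""))
  }
  o1 <- cluster_otus(dereplicate(reads))
  set.seed(1)
  o2 <- cluster_otus(dereplicate(reads[sample(nrow(reads)), ]))
  expect_identical(key(o1), key(o2))
})

test_that("co-member reads co-cluster at low error when members diverge", {
  fx <- get_fixture()
  comm <- build_mock_community(fx$fix$panel, 10, "offt01_syn")
  # low error relative to depth, so every member has a clean, abundant
  # centroid candidate; inter-member divergence is far above the 3% radius
  reads <- simulate_reads(comm, fx$amplicons,
                          read_sim_params(total_reads = 1100, seed = 23,
                                          substitution_rate = 0.0025,
                                          indel_rate = 0, chimera_rate = 0))
  otus <- cluster_otus(dereplicate(reads))
  mem <- otu_membership(otus)
  j <- dplyr::inner_join(mem, reads[, c("read_id", "truth_member_id")],
                         by = "read_id")
  # every sizeable OTU is pure (one member) and every member's reads land
  # predominantly in a single OTU
  big <- dplyr::filter(dplyr::count(j, otu_id), n >= 10)$otu_id
  purity <- j |>
    dplyr::filter(otu_id %in% big) |>
    dplyr::group_by(otu_id) |>
    dplyr::summarise(p = max(table(truth_member_id)) / dplyr::n())
  expect_true(all(purity$p == 1))
  member_cohesion <- j |>
    dplyr::group_by(truth_member_id) |>
    dplyr::summarise(top = max(table(otu_id)) / dplyr::n())
  expect_equal(nrow(member_cohesion), 11)
  expect_true(all(member_cohesion$top >= 0.9))
})

test_that("centroid FASTA round-trips through headers", {
  fx <- get_fixture()
  u <- dereplicate(tibble::tibble(
    read_id = paste0("r", 1:6),
    sequence = rep(fx$amplicons$sequence[1:3], 2)
  ))
  otus <- cluster_otus(u)
  fa <- withr::local_tempfile(fileext = ".fasta")
  pick_representatives(otus, fa)
  back <- read_representatives(fa)
  expect_equal(nrow(back), nrow(otus))
  expect_equal(back$otu_id, otus$otu_id)
  expect_equal(back$size, otus$size)
  expect_equal(back$centroid_sequence, otus$centroid_sequence)
  # empty OTU set gives an empty FASTA
  pick_representatives(otus[0, ], fa)
  expect_equal(length(Biostrings::readDNAStringSet(fa)), 0)
})

test_that("typing candidates include a full-length consensus even when
           every abundant unique is truncated", {
  fx <- get_fixture()
  amp <- fx$amplicons$sequence[1]
  set.seed(61)
  # abundant short prefixes, error-bearing reads of mixed length (some full
  # length), one clean full-length read at count 1, and an indel singleton
  reads <- tibble::tibble(
    read_id = paste0("r", 1:54),
    sequence = c(
      rep(substr(amp, 1, 210), 3),
      rep(substr(mutate_dna(amp, 0.005), 1, 240), 3),
      vapply(1:40, function(i) {
        substr(mutate_dna(amp, 0.005), 1, sample(200:500, 1))
      }, ""),
      vapply(1:6, function(i) mutate_dna(amp, 0.005), ""),
      amp,
      paste0(substr(amp, 1, 300), "A", substr(amp, 301, nchar(amp)))
    )
  )
  otus <- cluster_otus(dereplicate(reads))
  expect_equal(nrow(otus), 1)
  # the consensus candidate reconstructs the full-length molecule
  expect_true(amp %in% otus$candidate_seqs[[1]])
  cls <- classify_otus(otus, fx$fix$ancestral, fx$fix$panel)
  statuses <- unlist(cls[, grep("_status$", names(cls))])
  expect_false(any(statuses == "uncovered"))
  truth <- fx$fix$panel$gene_type[fx$fix$panel$id ==
                                    fx$amplicons$template_id[1]]
  expect_equal(cls$label, unname(expected_type_label[truth]))
})

test_that("OTU candidate FASTA round-trips", {
  fx <- get_fixture()
  u <- dereplicate(tibble::tibble(
    read_id = paste0("r", 1:6),
    sequence = rep(fx$amplicons$sequence[1:3], 2)
  ))
  otus <- cluster_otus(u)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_otu_candidates(otus, fa)
  back <- read_otu_candidates(fa)
  expect_equal(names(back), otus$otu_id)
  expect_equal(unname(back), lapply(otus$candidate_seqs, identity))
})
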
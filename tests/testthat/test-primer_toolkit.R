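test_that("IUPAC matching follows standard expansion semantics", {
  expect_true(iupac_match("N", "A"))
  expect_true(iupac_match("R", "G"))
  expect_false(iupac_match("R", "C"))
  expect_false(iupac_match("A", "N"))  # unknown template base never matches
  expect_error(iupac_match("Z", "A"), "IUPAC")
  expect_error(iupac_match("A", "R"), "template")
  # every code matches exactly its expansion set
  for (code in names(IUPAC_SETS)) {
    hits <- c("A", "C", "G", "T")[iupac_match(code,
                                              c("A", "C", "G", "T"))]
    expect_identical(hits, sort(iupac_expand(code)))
  }
})

test_that("binding sites are found for planted primers", {
  set.seed(5)
  primer <- degenerate_primer("p1", "ACGTACGTACGTACGTACGT", "forward")
  tpl <- paste0(random_dna(100), primer$sequence, random_dna(880))
  sites <- find_binding_sites(primer, tpl)
  plus <- dplyr::filter(sites, strand == "+")
  expect_true(any(plus$start == 101 & plus$mismatches == 0))
  # one internal substitution still binds, counted as one mismatch
  tpl2 <- tpl
  substr(tpl2, 105, 105) <- if (substr(tpl2, 105, 105) == "A") "C" else "A"
  s2 <- dplyr::filter(find_binding_sites(primer, tpl2), start == 101,
                      strand == "+")
  expect_equal(s2$mismatches, 1L)
  # primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites(primer, "ACGT")), 0)
})

test_that("3'-terminal window rejects mismatches and N never matches", {
  primer <- degenerate_primer("p", "AAAAAAAAAACCCCCCCCCC", "forward")
  tpl <- paste0("TTTT", "AAAAAAAAAACCCCCCCCCG", "TTTT")  # mismatch at 3' end
  sites <- find_binding_sites(primer, tpl,
                              pcr_params(max_mismatches = 2,
                                         three_prime_window = 3))
  expect_false(any(sites$strand == "+" & sites$start == 5))
  tplN <- paste0("TTTT", "AAAAANAAAACCCCCCCCCC", "TTTT")
  sN <- dplyr::filter(find_binding_sites(primer, tplN), strand == "+",
                      start == 5)
  expect_equal(sN$mismatches, 1L)
})

test_that("binding sites equal the exhaustive position-scan oracle", {
  set.seed(101)
  params <- pcr_params(max_mismatches = 2, three_prime_window = 3,
                       min_product = 1, max_product = 10000)
  for (i in 1:5) {
    tpl <- random_dna(3000)
    primer <- degenerate_primer("d", "GARTTYATGCAYAARGTNTGG", "forward")
    # plant two near-exact copies
    concrete <- "GAATTCATGCACAAGGTATGG"
    substr(tpl, 500, 520) <- concrete
    substr(tpl, 1500, 1520) <- concrete
    got <- find_binding_sites(primer, tpl, params)
    want <- oracle_binding_sites(primer$sequence, tpl, params)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("in-silico PCR emits convergent bounded products", {
  set.seed(7)
  fwd <- degenerate_primer("F", "ACGGTCAATGCGTCCTAGGA", "forward")
  rev <- degenerate_primer("R", "TACGGATCCTTGACGCATCA", "reverse")
  insert <- random_dna(360)
  tpl <- paste0(random_dna(49), fwd$sequence, insert, revcomp(rev$sequence),
                random_dna(100))
  prod <- in_silico_pcr(c(t1 = tpl), fwd, rev)
  expect_equal(nrow(prod), 1)
  expect_equal(prod$start, 50L)
  expect_equal(prod$length, 20L + 360L + 20L)
  expect_equal(prod$sequence,
               paste0(fwd$sequence, insert, revcomp(rev$sequence)))
  # too-short product excluded by the lower bound
  tpl_short <- paste0(random_dna(49), fwd$sequence, random_dna(100),
                      revcomp(rev$sequence), random_dna(50))
  expect_equal(nrow(in_silico_pcr(c(t1 = tpl_short), fwd, rev)), 0)
})

test_that("product sets equal the exhaustive pairing oracle", {
  set.seed(33)
  params <- pcr_params(max_mismatches = 1, min_product = 100,
                       max_product = 2000)
  fwd <- degenerate_primer("F", "ATGGARAAYTGGTAYCAYGA", "forward")
  rev <- degenerate_primer("R", "TCRTGRTACCARTTYTCCAT", "reverse")
  for (i in 1:5) {
    tpl <- random_dna(4000)
    # plant two forward sites upstream of one reverse site
    f1 <- "ATGGAGAATTGGTACCACGA"
    substr(tpl, 200, 219) <- f1
    substr(tpl, 700, 719) <- f1
    substr(tpl, 1500, 1519) <- revcomp("TCGTGGTACCAGTTTTCCAT")
    got <- in_silico_pcr(c(t = tpl), fwd, rev, params)
    want <- oracle_pcr_products(fwd$sequence, rev$sequence, tpl, params)
    expect_equal(as.data.frame(got[, c("start", "end", "strand", "length",
                                       "sequence")]),
                 as.data.frame(want))
    expect_gte(nrow(got), 2)  # both planted forward sites pair up
  }
})

test_that("every product re-amplifies to itself full length", {
  fx <- get_fixture()
  pair <- fx$fix$primers$round2_pair
  for (i in seq_len(nrow(fx$amplicons))) {
    re <- in_silico_pcr(c(p = fx$amplicons$sequence[i]), pair$forward,
                        pair$reverse)
    expect_true(any(re$length == fx$amplicons$length[i]))
  }
})

test_that("reverse-complementing templates mirrors product coordinates", {
  fx <- get_fixture()
  pair <- fx$fix$primers$round2_pair
  tpl <- fx$fix$panel$nt_sequence[1]
  fwdp <- in_silico_pcr(c(t = tpl), pair$forward, pair$reverse)
  revp <- in_silico_pcr(c(t = revcomp(tpl)), pair$forward, pair$reverse)
  expect_equal(nrow(fwdp), nrow(revp))
  n <- nchar(tpl)
  expect_setequal(paste(n - revp$end + 1, n - revp$start + 1),
                  paste(fwdp$start, fwdp$end))
  expect_setequal(revp$sequence, fwdp$sequence)
})

test_that("nested PCR products nest strictly inside round-1 products", {
  fx <- get_fixture()
  nested <- fx$amplicons
  r1 <- attr(nested, "round1")
  expect_gt(nrow(nested), 0)
  for (i in seq_len(nrow(nested))) {
    parents <- dplyr::filter(r1, template_id == nested$template_id[i],
                             start <= nested$start[i],
                             end >= nested$end[i])
    expect_gt(nrow(parents), 0)
    expect_true(all(parents$start < nested$start[i] |
                      parents$end > nested$end[i]))
  }
  expect_true(all(nested$pcr_round == 2L))
  # a template with round-2 sites but no round-1 sites yields nothing
  inner_only <- substr(fx$fix$panel$nt_sequence[1], 76, 591)
  lone <- nested_pcr(c(t = inner_only), fx$fix$primers$round1_pairs,
                     fx$fix$primers$round2_pair)
  expect_equal(nrow(lone), 0)
})

test_that("nested PCR equals per-product round-2 runs after dedup", {
  fx <- get_fixture()
  r1 <- attr(fx$amplicons, "round1")
  pair <- fx$fix$primers$round2_pair
  manual <- purrr::map_dfr(seq_len(nrow(r1)), function(i) {
    p <- in_silico_pcr(c(x = r1$sequence[i]), pair$forward, pair$reverse)
    if (nrow(p) == 0) return(p)
    p$abs_start <- ifelse(r1$strand[i] == "+", r1$start[i] + p$start - 1L,
                          r1$end[i] - p$end + 1L)
    p$abs_end <- ifelse(r1$strand[i] == "+", r1$start[i] + p$end - 1L,
                        r1$end[i] - p$start + 1L)
    p$template_id <- r1$template_id[i]
    p
  }) |>
    dplyr::distinct(template_id, abs_start, abs_end)
  got <- dplyr::distinct(fx$amplicons, template_id, start, end)
  expect_setequal(paste(got$template_id, got$start, got$end),
                  paste(manual$template_id, manual$abs_start,
                        manual$abs_end))
})

test_that("conserved-region scan matches a per-column labelling oracle", {
  # identical sequences: one region spanning everything
  aln <- rep("MKWEEL", 5)
  reg <- scan_conserved_regions(aln, min_conservation = 1, min_length = 2)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1)
  expect_equal(reg$end, 6)
  expect_equal(reg$motif, "MKWEEL")
  # a fully variable column splits two blocks
  aln2 <- c("MKWAEL", "MKWCEL", "MKWDEL", "MKWFEL", "MKWGEL")
  reg2 <- scan_conserved_regions(aln2, min_conservation = 1, min_length = 2)
  expect_equal(nrow(reg2), 2)
  expect_equal(reg2$start, c(1, 5))
  expect_equal(reg2$end, c(3, 6))
  # random alignments vs oracle
  set.seed(9)
  for (i in 1:5) {
    mat <- matrix(sample(c("A", "C", "D", "-"), 8 * 40, replace = TRUE,
                         prob = c(.45, .3, .15, .1)), nrow = 8)
    aln3 <- apply(mat, 1, paste, collapse = "")
    got <- scan_conserved_regions(aln3, min_conservation = 0.6,
                                  min_length = 3)
    # oracle: label each column, then extract runs in ref coordinates
    ref <- mat[1, ]
    good <- logical(40)
    mode_res <- character(40)
    for (j in 1:40) {
      col <- mat[, j][mat[, j] != "-"]
      if (length(col) == 0) next
      tab <- sort(table(col), decreasing = TRUE)
      good[j] <- tab[1] / 8 >= 0.6 && ref[j] != "-"
      mode_res[j] <- names(tab)[1]
    }
    runs <- rle(good)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    ref_pos <- cumsum(ref != "-")
    keep <- which(runs$values & runs$lengths >= 3)
    expect_equal(nrow(got), length(keep))
    for (k in seq_along(keep)) {
      expect_equal(got$start[k], ref_pos[starts[keep[k]]])
      expect_equal(got$end[k], ref_pos[ends[keep[k]]])
      expect_equal(got$motif[k],
                   paste(mode_res[starts[keep[k]]:ends[keep[k]]],
                         collapse = ""))
    }
  }
})

test_that("primer design back-translates motifs into covering IUPAC strings", {
  expect_equal(design_degenerate_primer("MW")$sequence, "ATGTGG")
  expect_equal(design_degenerate_primer("MW")$degeneracy, 1)
  expect_equal(design_degenerate_primer("W", "reverse")$sequence, "CCA")
  ef <- design_degenerate_primer("EF")
  # expansion set equals the enumeration of all codon concatenations
  expand_iupac <- function(s) {
    sets <- lapply(strsplit(s, "")[[1]], iupac_expand)
    apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
          paste, collapse = "")
  }
  tab <- standard_codon_table()
  enum <- as.vector(outer(tab[["E"]], tab[["F"]], paste0))
  expect_setequal(expand_iupac(ef$sequence), enum)
  expect_equal(ef$degeneracy, 4)
  expect_error(design_degenerate_primer("MXW"), "X")
  # serine (6 codons over two boxes) inflates degeneracy beyond its codons,
  # but the expansion still covers every codon
  s <- design_degenerate_primer("SSSSSS", max_degeneracy = 1e9)
  expect_true(all(tab[["S"]] %in% expand_iupac(substr(s$sequence, 1, 3))))
  expect_error(design_degenerate_primer("SSSSSS"), "degeneracy")
})
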
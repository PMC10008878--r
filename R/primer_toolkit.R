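# Degenerate primers, binding-site search, single-round and nested in-silico
# PCR, conserved-region scanning and back-translation primer design.
#
# Annealing model: Hamming mismatches only (no indels), a configurable
# mismatch budget, and a protected 3'-terminal window in which no mismatch is
# allowed. Coordinates are 1-based inclusive on the plus strand.

#' Define a degenerate primer
#'
#' @param name Primer name.
#' @param sequence IUPAC DNA string, written 5' to 3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return One-row tibble (`name`, `sequence`, `orientation`).
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!.is_iupac_dna(sequence)) {
    abort(paste0("primer '", name, "' contains non-IUPAC characters"))
  }
  if (nchar(sequence) < 10) {
    abort(paste0("primer '", name, "' is shorter than 10 nt"))
  }
  tibble::tibble(name = name, sequence = sequence, orientation = orientation)
}

#' In-silico PCR parameters
#'
#' Defaults: up to 2 mismatches per primer, none in the 3'-terminal 3 nt,
#' and products restricted to 200-600 nt (the trimmed amplicon length range
#' observed for this assay class).
#'
#' @param max_mismatches Maximum mismatches tolerated per primer site.
#' @param three_prime_window Number of 3'-terminal bases in which no
#'   mismatch is allowed.
#' @param min_product,max_product Product length bounds (nt, inclusive).
#' @return A `pcr_params` list.
#' @export
pcr_params <- function(max_mismatches = 2L, three_prime_window = 3L,
                       min_product = 200L, max_product = 600L) {
  stopifnot(max_mismatches >= 0, three_prime_window >= 0,
            min_product <= max_product, min_product >= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_window = as.integer(three_prime_window),
                 min_product = as.integer(min_product),
                 max_product = as.integer(max_product)),
            class = "pcr_params")
}

# Encode a plain-DNA template into integer codes over A,C,G,T,N.
.encode_template <- function(template) {
  chars <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    abort("template contains characters outside {A,C,G,T,N}")
  }
  code
}

# Mismatch counts of a primer against every start position of a template,
# one strand. Returns a list(total =, window =) of integer vectors indexed by
# start position; `window_positions` are primer positions (1-based in the
# primer string as laid on the + strand) protected against mismatches.
.scan_primer <- function(primer_chars, tpl_code, window_positions) {
  L <- length(primer_chars)
  n <- length(tpl_code)
  n_starts <- n - L + 1
  if (n_starts < 1) return(list(total = integer(0), window = integer(0)))
  total <- integer(n_starts)
  window <- integer(n_starts)
  mm <- !.iupac_match_matrix[, c("A", "C", "G", "T", "N")]
  for (j in seq_len(L)) {
    mis <- mm[primer_chars[j], tpl_code[j:(j + n_starts - 1)]]
    total <- total + mis
    if (j %in% window_positions) window <- window + mis
  }
  list(total = total, window = window)
}

#' Find primer binding sites on a template
#'
#' Scans both strands. A site on strand `+` means the primer sequence (5'-3')
#' matches the plus strand left-to-right (extension rightwards); a site on
#' strand `-` means the primer matches the reverse complement (extension
#' leftwards), reported as its footprint interval on the plus strand. An `N`
#' in the template counts as a mismatch.
#'
#' @param primer One-row primer tibble from [degenerate_primer()].
#' @param template DNA string (`A/C/G/T/N`).
#' @param params [pcr_params()].
#' @return Tibble `strand`, `start`, `end` (1-based inclusive, plus strand),
#'   `mismatches`, sorted by (strand, start). A primer longer than the
#'   template yields an empty tibble.
#' @export
find_binding_sites <- function(primer, template, params = pcr_params()) {
  tpl_code <- .encode_template(template)
  L <- nchar(primer$sequence[1])
  w <- min(params$three_prime_window, L)
  empty <- tibble::tibble(strand = character(), start = integer(),
                          end = integer(), mismatches = integer())
  if (L > length(tpl_code)) return(empty)

  # + strand: primer as written; 3' end is the rightmost primer base.
  pc <- strsplit(primer$sequence[1], "", fixed = TRUE)[[1]]
  fw <- .scan_primer(pc, tpl_code, window_positions = seq(L - w + 1, length.out = w))
  # - strand: the reverse complement of the primer lies on the + strand;
  # the primer's 3' end maps to the leftmost base of the footprint.
  rc <- strsplit(revcomp(primer$sequence[1]), "", fixed = TRUE)[[1]]
  rv <- .scan_primer(rc, tpl_code, window_positions = seq_len(w))

  keep_fw <- which(fw$total <= params$max_mismatches & fw$window == 0)
  keep_rv <- which(rv$total <= params$max_mismatches & rv$window == 0)
  out <- dplyr::bind_rows(
    tibble::tibble(strand = "+", start = as.integer(keep_fw),
                   end = as.integer(keep_fw + L - 1L),
                   mismatches = as.integer(fw$total[keep_fw])),
    tibble::tibble(strand = "-", start = as.integer(keep_rv),
                   end = as.integer(keep_rv + L - 1L),
                   mismatches = as.integer(rv$total[keep_rv]))
  )
  dplyr::arrange(out, .data$strand, .data$start)
}

#' Run single-round in-silico PCR
#'
#' Pairs convergent forward/reverse binding sites on each template and emits
#' every product within the length bounds (no shortest-product heuristic;
#' downstream filtering decides). Product sequences include both primer
#' footprints. For a forward site on `+` and a reverse site on `-` the
#' product is reported on `+`; the mirrored configuration is reported on `-`
#' with a reverse-complemented sequence.
#'
#' @param templates Tibble with columns `id`, `sequence` (or a named
#'   character vector).
#' @param forward,reverse One-row primer tibbles.
#' @param params [pcr_params()].
#' @return Tibble `template_id`, `start`, `end`, `strand`, `length`,
#'   `sequence`, `pair_name`, `pcr_round` in deterministic order.
#' @export
in_silico_pcr <- function(templates, forward, reverse, params = pcr_params()) {
  templates <- .as_template_tbl(templates)
  pair_name <- paste0(forward$name[1], "/", reverse$name[1])
  res <- purrr::map_dfr(seq_len(nrow(templates)), function(i) {
    tpl <- templates$sequence[i]
    fs <- find_binding_sites(forward, tpl, params)
    rs <- find_binding_sites(reverse, tpl, params)
    plus <- .pair_sites(dplyr::filter(fs, .data$strand == "+"),
                        dplyr::filter(rs, .data$strand == "-"),
                        tpl, params, product_strand = "+")
    minus <- .pair_sites(dplyr::filter(rs, .data$strand == "+"),
                         dplyr::filter(fs, .data$strand == "-"),
                         tpl, params, product_strand = "-")
    out <- dplyr::bind_rows(plus, minus)
    if (nrow(out) == 0) return(out)
    out$template_id <- templates$id[i]
    out
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(template_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          length = integer(), sequence = character(),
                          pair_name = character(), pcr_round = integer()))
  }
  res$pair_name <- pair_name
  res$pcr_round <- 1L
  res <- dplyr::distinct(res, .data$template_id, .data$start, .data$end,
                         .data$strand, .keep_all = TRUE)
  res[, c("template_id", "start", "end", "strand", "length", "sequence",
          "pair_name", "pcr_round")] |>
    dplyr::arrange(match(.data$template_id, templates$id), .data$strand,
                   .data$start, .data$end)
}

# left: sites whose primer extends rightwards (+ sites of the left primer);
# right: sites whose primer extends leftwards (- sites of the right primer).
.pair_sites <- function(left, right, tpl, params, product_strand) {
  if (nrow(left) == 0 || nrow(right) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          sequence = character()))
  }
  combos <- tidyr::expand_grid(ls = seq_len(nrow(left)),
                               rs = seq_len(nrow(right)))
  start <- left$start[combos$ls]
  end <- right$end[combos$rs]
  len <- end - start + 1L
  ok <- start <= right$start[combos$rs] & left$end[combos$ls] <= end &
    len >= params$min_product & len <= params$max_product
  start <- start[ok]; end <- end[ok]; len <- len[ok]
  if (length(start) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          sequence = character()))
  }
  seqs <- substring(tpl, start, end)
  if (product_strand == "-") seqs <- revcomp(seqs)
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 strand = product_strand, length = as.integer(len),
                 sequence = toupper(seqs))
}

.as_template_tbl <- function(templates) {
  if (is.character(templates)) {
    if (is.null(names(templates))) {
      names(templates) <- paste0("template_", seq_along(templates))
    }
    templates <- tibble::tibble(id = names(templates),
                                sequence = unname(templates))
  }
  tibble::as_tibble(templates)[, c("id", "sequence")]
}

#' Run nested in-silico PCR
#'
#' Round 1 amplifies each template with every first-round primer pair; the
#' de-duplicated union of round-1 products (by template, interval and strand)
#' then serves as the only templates for round 2, mirroring a nested PCR in
#' which second-round primers must bind inside first-round products.
#' Round-2 coordinates are mapped back to the original templates.
#'
#' @param templates Templates as for [in_silico_pcr()].
#' @param round1_pairs List of `list(forward = , reverse = )` primer pairs.
#' @param round2_pair A `list(forward = , reverse = )` pair.
#' @param params [pcr_params()] for round 2 (and round 1 unless
#'   `params_round1` is given).
#' @param params_round1 Optional separate [pcr_params()] for round 1.
#' @return Tibble of round-2 products (`pcr_round == 2`) with absolute
#'   coordinates on the original templates, plus attribute `round1` holding
#'   the round-1 product tibble.
#' @export
nested_pcr <- function(templates, round1_pairs, round2_pair,
                       params = pcr_params(), params_round1 = params) {
  templates <- .as_template_tbl(templates)
  r1 <- purrr::map_dfr(round1_pairs, function(pair) {
    in_silico_pcr(templates, pair$forward, pair$reverse, params_round1)
  }) |>
    dplyr::distinct(.data$template_id, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE)
  if (nrow(r1) == 0) {
    out <- r1
    attr(out, "round1") <- r1
    return(out)
  }
  r1$product_id <- sprintf("%s:%d-%d%s", r1$template_id, r1$start, r1$end,
                           r1$strand)
  inner <- in_silico_pcr(
    tibble::tibble(id = r1$product_id, sequence = r1$sequence),
    round2_pair$forward, round2_pair$reverse, params
  )
  if (nrow(inner) > 0) {
    parent <- r1[match(inner$template_id, r1$product_id), ]
    abs_start <- ifelse(parent$strand == "+",
                        parent$start + inner$start - 1L,
                        parent$end - inner$end + 1L)
    abs_end <- ifelse(parent$strand == "+",
                      parent$start + inner$end - 1L,
                      parent$end - inner$start + 1L)
    abs_strand <- ifelse(inner$strand == "+", parent$strand,
                         ifelse(parent$strand == "+", "-", "+"))
    inner$template_id <- parent$template_id
    inner$start <- as.integer(abs_start)
    inner$end <- as.integer(abs_end)
    inner$strand <- abs_strand
    inner$pcr_round <- 2L
    inner <- dplyr::distinct(inner, .data$template_id, .data$start,
                             .data$end, .data$strand, .keep_all = TRUE) |>
      dplyr::arrange(match(.data$template_id, templates$id), .data$strand,
                     .data$start, .data$end)
  }
  attr(inner, "round1") <- r1
  inner
}

#' Scan a protein alignment for conserved regions
#'
#' A column is conserved when its modal non-gap residue occurs in at least
#' `min_conservation` of the sequences and the first (reference) sequence is
#' not gapped there. Maximal runs of at least `min_length` conserved columns
#' are reported in reference coordinates (gaps removed), with the motif made
#' of the modal residues.
#'
#' @param aligned_panel Character vector of equal-length aligned protein
#'   strings, gaps as `-`; the first sequence is the coordinate reference.
#' @param min_conservation Minimum modal-residue fraction (of all sequences).
#' @param min_length Minimum region length in columns.
#' @return Tibble `label`, `start`, `end`, `motif`.
#' @export
scan_conserved_regions <- function(aligned_panel, min_conservation = 0.9,
                                   min_length = 6L) {
  lens <- nchar(aligned_panel)
  if (length(unique(lens)) != 1) abort("aligned sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(aligned_panel), "", fixed = TRUE))
  n <- nrow(mat)
  ref <- mat[1, ]
  ref_pos <- cumsum(ref != "-")
  col_stats <- purrr::map(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0) return(list(ok = FALSE, mode = NA_character_))
    tab <- sort(table(col), decreasing = TRUE)
    list(ok = tab[1] / n >= min_conservation, mode = names(tab)[1])
  })
  good <- vapply(col_stats, `[[`, TRUE, "ok") & ref != "-"
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  out <- purrr::map_dfr(which(keep), function(k) {
    cols <- starts[k]:ends[k]
    tibble::tibble(
      start = ref_pos[starts[k]],
      end = ref_pos[ends[k]],
      motif = paste(vapply(col_stats[cols], `[[`, "", "mode"), collapse = "")
    )
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(label = character(), start = integer(),
                          end = integer(), motif = character()))
  }
  out$label <- paste0("CR", seq_len(nrow(out)))
  out[, c("label", "start", "end", "motif")]
}

#' Design a degenerate primer by back-translation
#'
#' Back-translates an amino-acid motif into the minimal IUPAC string whose
#' expansion covers every codon combination of the motif. Degeneracy is the
#' product of per-position expansion sizes; designs above `max_degeneracy`
#' fail loudly as unusable. Reverse-orientation primers are
#' reverse-complemented.
#'
#' @param motif Amino-acid motif (at least 4 residues, no `X` or gaps).
#' @param orientation `"forward"` or `"reverse"`.
#' @param name Primer name (default derived from the motif).
#' @param codon_table Named list amino acid -> codons; defaults to the
#'   standard genetic code.
#' @param max_degeneracy Degeneracy cap (default 4096).
#' @return One-row tibble `name`, `sequence`, `orientation`, `degeneracy`,
#'   `motif`.
#' @export
design_degenerate_primer <- function(motif, orientation = c("forward", "reverse"),
                                     name = NULL, codon_table = NULL,
                                     max_degeneracy = 4096) {
  orientation <- match.arg(orientation)
  motif <- toupper(motif)
  if (grepl("[X*-]", motif)) abort("motif must not contain 'X', '*' or gaps")
  aas <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(aas %in% AA_ALPHABET20)) {
    abort("motif contains a non-standard amino acid")
  }
  if (is.null(codon_table)) codon_table <- standard_codon_table()
  per_pos <- purrr::map(aas, function(a) {
    codons <- codon_table[[a]]
    purrr::map_chr(1:3, function(k) {
      iupac_from_bases(substring(codons, k, k))
    })
  })
  seq <- paste(unlist(per_pos), collapse = "")
  degeneracy <- prod(nchar(vapply(strsplit(seq, "", fixed = TRUE)[[1]],
                                  function(cd) paste(iupac_expand(cd), collapse = ""),
                                  "")))
  if (degeneracy > max_degeneracy) {
    abort(sprintf("designed primer degeneracy %d exceeds cap %d",
                  degeneracy, as.integer(max_degeneracy)))
  }
  if (orientation == "reverse") seq <- revcomp(seq)
  if (is.null(name)) name <- paste0(motif, "_", substr(orientation, 1, 1))
  # built directly: design admits short motifs for inspection, while
  # degenerate_primer() enforces the >= 10 nt length a usable primer needs
  tibble::tibble(name = name, sequence = seq, orientation = orientation,
                 degeneracy = degeneracy, motif = motif)
}

#' Standard genetic code as amino acid -> codon list
#' @return Named list mapping one-letter amino acids (and `*`) to codons.
#' @export
standard_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Write amplicon products to FASTA
#'
#' Headers follow `template_id|start-end|pair|round`.
#' @param products Product tibble from [in_silico_pcr()] or [nested_pcr()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_amplicons <- function(products, path) {
  seqs <- Biostrings::DNAStringSet(products$sequence)
  names(seqs) <- sprintf("%s|%d-%d|%s|%d", products$template_id,
                         products$start, products$end, products$pair_name,
                         products$pcr_round)
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}
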
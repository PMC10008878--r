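# Translation, best-frame alignment to the ancestral reference, catalytic
# residue calling and rule-based MnP/VP/LiP typing.
#
# The decision rules: the surface tryptophan W171 distinguishes peroxidases
# able to oxidize non-phenolic lignin (VP/LiP); the acidic triad E37, E41,
# D183 forms the Mn(II)-binding site of MnPs and VPs. A sequence carrying
# W171 together with the Mn site evidence (D183, or both glutamates, or an
# MnP nearest reference) is a VP; W171 without that evidence is a LiP; no
# W171 with at least two of {E37, E41, D183} is an MnP; the remainder of
# alignable class II sequences is "rest-AA2", and sequences with no credible
# relationship to the family are "non-AA2".

#' Translate a DNA sequence in all six frames
#'
#' Standard genetic code, stops rendered `*`, trailing partial codons
#' dropped; frames -1..-3 read the reverse complement.
#'
#' @param seq DNA string of length >= 3.
#' @return Named character vector of the six translations
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(unname(seq))
  if (nchar(seq) < 3) abort("sequence shorter than one codon")
  rc <- revcomp(seq)
  frames <- c(`+1` = substr(seq, 1, nchar(seq)),
              `+2` = substr(seq, 2, nchar(seq)),
              `+3` = substr(seq, 3, nchar(seq)),
              `-1` = substr(rc, 1, nchar(rc)),
              `-2` = substr(rc, 2, nchar(rc)),
              `-3` = substr(rc, 3, nchar(rc)))
  frames <- vapply(frames, function(s) {
    substr(s, 1, 3 * (nchar(s) %/% 3))
  }, "")
  keep <- nchar(frames) >= 3
  out <- rep(NA_character_, 6)
  names(out) <- names(frames)
  out[keep] <- as.character(
    Biostrings::translate(Biostrings::DNAStringSet(frames[keep]),
                          if.fuzzy.codon = "X")
  )
  out
}

#' Classifier thresholds
#'
#' @param score_floor Minimum best-frame local alignment score (BLOSUM62,
#'   affine gaps) for the amplicon to count as aligned to the ancestral
#'   reference. Every amplified molecule carries the conserved primer
#'   footprints, which align to the ancestral reference yet carry no family
#'   information, so the floor must demand similarity beyond them: the
#'   default was calibrated with [calibrate_score_floor()] on random
#'   sequences bearing in-frame primer footprints at both ends, so that such
#'   sequences pass in under 1 percent of cases.
#' @param panel_identity_floor Minimum identity to the nearest panel
#'   reference for an unalignable sequence to escape the non-AA2 label.
#' @param min_covered Minimum number of framework positions that must lie in
#'   the aligned span for a confident family call (default 2).
#' @param gap_opening,gap_extension Affine gap penalties for protein
#'   alignments.
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(score_floor = 100, panel_identity_floor = 0.6,
                              min_covered = 2L, gap_opening = 10,
                              gap_extension = 0.5) {
  structure(list(score_floor = score_floor,
                 panel_identity_floor = panel_identity_floor,
                 min_covered = as.integer(min_covered),
                 gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "classifier_params")
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Align an amplicon to the ancestral reference in its best frame
#'
#' Translates all six frames and locally aligns each against the ancestral
#' protein (BLOSUM62, affine gaps); the highest-scoring frame wins, ties
#' broken in frame order `+1, +2, +3, -1, -2, -3`. An internal stop codon in
#' the aligned query region sets the `internal_stop` flag (it never rejects
#' the amplicon: genomic amplicons may span introns). A best score below the
#' significance floor marks the alignment non-significant.
#'
#' @param amplicon DNA string.
#' @param ancestral An `ancestral_ref`.
#' @param params [classifier_params()].
#' @return A `frame_alignment` list: `frame`, `score`, `significant`,
#'   `identity_to_ref`, `ref_start`, `ref_end` (aligned span on the
#'   ancestral protein), `query_protein` (full best-frame translation),
#'   `column_map` (character vector indexed by ancestral position: the query
#'   residue aligned there, `NA` outside the span, `"-"` at a deletion),
#'   `internal_stop`.
#' @export
best_frame_alignment <- function(amplicon, ancestral,
                                 params = classifier_params()) {
  frames <- six_frame_translate(amplicon)
  ok <- !is.na(frames)
  subj <- Biostrings::AAString(ancestral$aa_sequence)
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(frames[ok]), subj, type = "local",
    substitutionMatrix = .blosum62(),
    gapOpening = params$gap_opening, gapExtension = params$gap_extension
  )
  scores <- rep(-Inf, 6)
  scores[ok] <- Biostrings::score(alns)
  best <- which.max(scores)  # ties: first in frame order
  aln <- alns[which(which(ok) == best)]
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  ref_start <- Biostrings::start(Biostrings::subject(aln))
  ref_end <- Biostrings::end(Biostrings::subject(aln))
  len <- nchar(ancestral$aa_sequence)
  column_map <- rep(NA_character_, len)
  p_chars <- strsplit(pat, "", fixed = TRUE)[[1]]
  s_chars <- strsplit(sub, "", fixed = TRUE)[[1]]
  rp <- ref_start - 1L
  for (k in seq_along(s_chars)) {
    if (s_chars[k] != "-") {
      rp <- rp + 1L
      column_map[rp] <- p_chars[k]
    }
    # query residues inserted relative to the reference carry no ancestral
    # coordinate and are skipped
  }
  aligned_query <- gsub("-", "", pat)
  structure(list(
    frame = names(frames)[best],
    score = scores[best],
    significant = is.finite(scores[best]) && scores[best] >= params$score_floor,
    identity_to_ref = Biostrings::pid(aln, type = "PID1") / 100,
    ref_start = ref_start,
    ref_end = ref_end,
    query_protein = frames[[best]],
    column_map = column_map,
    internal_stop = grepl("\\*", aligned_query)
  ), class = "frame_alignment")
}

#' Empirically calibrate the alignment significance floor
#'
#' Scores `n` random uniform DNA sequences of the given length against the
#' ancestral reference and returns the `1 - target_fp` score quantile: a
#' floor at that value lets such sequences through at about the target
#' false-positive rate. Because every PCR product necessarily carries the
#' conserved primer footprints, `embed_motifs` plants in-frame
#' back-translations of the given amino-acid motifs at the 5' and 3' ends of
#' each random sequence, calibrating against the hardest realistic
#' negatives: amplifiable molecules unrelated to the family.
#'
#' @param ancestral An `ancestral_ref`.
#' @param n Number of random sequences.
#' @param read_length Length of the random sequences (nt).
#' @param target_fp Target false-positive rate (default 0.01).
#' @param seed RNG seed.
#' @param embed_motifs Optional character vector of amino-acid motifs (e.g.
#'   the primer-design motifs) embedded in frame at the sequence ends.
#' @param params [classifier_params()] for the alignment scoring.
#' @return The calibrated score floor (numeric).
#' @export
calibrate_score_floor <- function(ancestral, n = 1000, read_length = 500,
                                  target_fp = 0.01, seed = 1,
                                  embed_motifs = NULL,
                                  params = classifier_params()) {
  with_seed(seed, {
    scores <- vapply(seq_len(n), function(i) {
      if (is.null(embed_motifs)) {
        s <- paste(sample(c("A", "C", "G", "T"), read_length, TRUE),
                   collapse = "")
      } else {
        ends <- vapply(embed_motifs, back_translate_random, "")
        core <- max(3, read_length - sum(nchar(ends)))
        core <- 3L * (core %/% 3L)  # keep both footprints in frame
        mid <- paste(sample(c("A", "C", "G", "T"), core, TRUE), collapse = "")
        s <- paste0(ends[1], mid, paste(ends[-1], collapse = ""))
      }
      best_frame_alignment(s, ancestral,
                           classifier_params(score_floor = -Inf))$score
    }, 0)
    unname(stats::quantile(scores, 1 - target_fp, type = 1))
  })
}

#' Call the catalytic framework residues
#'
#' For each residue spec: `uncovered` when the position lies outside the
#' aligned span (or nothing aligned); `present` when the query residue
#' aligned at the position equals the expected amino acid; `shifted` when
#' the expected residue sits within the residue specification's tolerance in ancestral
#' columns (nearest offset wins, downstream preferred on ties, signed offset
#' reported); `absent` otherwise.
#'
#' @param aln `frame_alignment` from [best_frame_alignment()], or one whose
#'   `significant` is `FALSE` (all calls then `uncovered`).
#' @param specs Residue-spec tibble (default [default_residue_specs()]).
#' @return Tibble `name`, `status`, `offset`.
#' @export
call_residues <- function(aln, specs = default_residue_specs()) {
  purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    pos <- specs$position[i]
    expected <- specs$expected_aa[i]
    tol <- specs$tolerance[i]
    if (!isTRUE(aln$significant) ||
        pos < aln$ref_start || pos > aln$ref_end) {
      return(tibble::tibble(name = specs$name[i], status = "uncovered",
                            offset = NA_integer_))
    }
    if (identical(aln$column_map[pos], expected)) {
      return(tibble::tibble(name = specs$name[i], status = "present",
                            offset = 0L))
    }
    if (tol > 0) {
      for (k in seq_len(tol)) {
        for (d in c(k, -k)) {  # downstream preferred on tie
          p2 <- pos + d
          if (p2 >= aln$ref_start && p2 <= aln$ref_end &&
              identical(aln$column_map[p2], expected)) {
            return(tibble::tibble(name = specs$name[i], status = "shifted",
                                  offset = as.integer(d)))
          }
        }
      }
    }
    tibble::tibble(name = specs$name[i], status = "absent",
                   offset = NA_integer_)
  })
}

#' Find the nearest reference in the panel
#'
#' Aligns the query protein end-to-end against each panel protein (the query
#' global, the reference locally trimmed: amplicons are fragments of
#' full-length genes) and returns the best identity; ties go to the earlier
#' panel record. Panel members without a stored protein are translated from
#' their coding sequence in frame +1.
#'
#' @param query_protein Protein string.
#' @param panel Panel tibble.
#' @param params [classifier_params()].
#' @return One-row tibble `nearest_ref_id`, `nearest_ref_identity`,
#'   `nearest_ref_gene_type`.
#' @export
nearest_reference <- function(query_protein, panel,
                              params = classifier_params()) {
  if (nrow(panel) == 0) abort("empty reference panel")
  aa <- panel_proteins(panel)
  mat <- .blosum62()
  q <- Biostrings::AAStringSet(query_protein)
  best_i <- 1L
  best_id <- -Inf
  for (i in seq_len(nrow(panel))) {
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(aa[i]), type = "global-local",
      substitutionMatrix = mat, gapOpening = params$gap_opening,
      gapExtension = params$gap_extension
    )
    idy <- Biostrings::pid(aln, type = "PID1") / 100
    if (idy > best_id) { best_id <- idy; best_i <- i }
  }
  tibble::tibble(nearest_ref_id = panel$id[best_i],
                 nearest_ref_identity = best_id,
                 nearest_ref_gene_type = panel$gene_type[best_i])
}

#' Protein sequences of a panel
#'
#' Stored `aa_sequence` when present, otherwise the frame +1 translation of
#' the coding sequence (trailing stop trimmed).
#' @param panel Panel tibble.
#' @return Character vector of proteins, one per panel row.
#' @export
panel_proteins <- function(panel) {
  vapply(seq_len(nrow(panel)), function(i) {
    if (!is.na(panel$aa_sequence[i])) return(panel$aa_sequence[i])
    aa <- six_frame_translate(panel$nt_sequence[i])[["+1"]]
    sub("\\*$", "", aa)
  }, "")
}

#' Apply the peroxidase typing rules
#'
#' Precedence (a residue counts as detected when `present` or `shifted`;
#' shifted detections are additionally flagged):
#' 1. no significant ancestral alignment and nearest-reference identity
#'    below the panel floor: `non-AA2`;
#' 2. fewer than `min_covered` framework positions covered: `rest-AA2`
#'    with flag `low-coverage`;
#' 3. W171 detected: `VP` if D183 detected, or both E37 and E41 detected,
#'    or the nearest reference is an MnP; otherwise `LiP`;
#' 4. W171 not detected: `MnP` if at least two of {E37, E41, D183} detected;
#'    otherwise `rest-AA2`.
#'
#' @param calls Residue-call tibble from [call_residues()].
#' @param nearest One-row tibble from [nearest_reference()] (or `NULL` for
#'   no panel evidence).
#' @param significant Logical: did the amplicon align to the ancestral
#'   reference above the score floor?
#' @param internal_stop Logical flag from the frame alignment.
#' @param params [classifier_params()].
#' @return One-row tibble `label`, `flags` (comma-separated, may be empty).
#' @export
classify_peroxidase <- function(calls, nearest = NULL, significant = TRUE,
                                internal_stop = FALSE,
                                params = classifier_params()) {
  detected <- function(nm) {
    calls$status[calls$name == nm] %in% c("present", "shifted")
  }
  shifted <- function(nm) calls$status[calls$name == nm] == "shifted"
  flags <- character(0)
  if (internal_stop) flags <- c(flags, "internal-stop")
  if (shifted("W171")) flags <- c(flags, "shifted-Trp")
  near_id <- if (is.null(nearest)) 0 else nearest$nearest_ref_identity
  near_type <- if (is.null(nearest)) "unknown" else nearest$nearest_ref_gene_type
  n_covered <- sum(calls$status != "uncovered")
  label <- if (!significant && near_id < params$panel_identity_floor) {
    "non-AA2"
  } else if (n_covered < params$min_covered) {
    flags <- c(flags, "low-coverage")
    "rest-AA2"
  } else if (detected("W171")) {
    if (detected("D183") || (detected("E37") && detected("E41")) ||
        identical(near_type, "MnP")) "VP" else "LiP"
  } else {
    if (sum(c(detected("E37"), detected("E41"), detected("D183"))) >= 2) {
      "MnP"
    } else {
      "rest-AA2"
    }
  }
  tibble::tibble(label = label, flags = paste(flags, collapse = ","))
}

#' Classify a set of sequences against ancestral reference and panel
#'
#' The full per-sequence chain: best-frame alignment, residue calling,
#' nearest-reference lookup and rule application.
#'
#' @param seqs Tibble with `id` and `sequence` columns.
#' @param ancestral An `ancestral_ref`.
#' @param panel Panel tibble.
#' @param params [classifier_params()].
#' @return Tibble with one row per sequence: `id`, `label`, per-residue
#'   status/offset columns (e.g. `E37_status`, `E37_offset`), `frame`,
#'   `score`, `identity_to_ref`, `nearest_ref_id`, `nearest_ref_identity`,
#'   `nearest_ref_gene_type`, `flags`.
#' @export
classify_sequences <- function(seqs, ancestral, panel,
                               params = classifier_params()) {
  specs <- ancestral$residues
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    aln <- best_frame_alignment(seqs$sequence[i], ancestral, params)
    calls <- call_residues(aln, specs)
    near <- nearest_reference(aln$query_protein, panel, params)
    cls <- classify_peroxidase(calls, near, aln$significant,
                               aln$internal_stop, params)
    status <- stats::setNames(calls$status, paste0(calls$name, "_status"))
    offset <- stats::setNames(calls$offset, paste0(calls$name, "_offset"))
    dplyr::bind_cols(
      tibble::tibble(id = seqs$id[i], label = cls$label),
      tibble::as_tibble(as.list(status)),
      tibble::as_tibble(as.list(offset)),
      tibble::tibble(frame = aln$frame, score = aln$score,
                     identity_to_ref = aln$identity_to_ref),
      near,
      tibble::tibble(flags = cls$flags)
    )
  })
}

#' Classify OTUs and propagate member counts
#'
#' Classifies each OTU from its typing candidates (the OTU's most abundant
#' uniques, see [cluster_otus()]) and keeps the candidate whose alignment
#' covers the most framework residues (ties: higher alignment score, then
#' candidate order). Weighing a few abundant uniques instead of the single
#' greedy centroid guards against 3'-trimmed centroids whose alignment
#' cannot reach the downstream residues, and against indel-bearing reads
#' whose frameshifts truncate the aligned span. Without a `candidate_seqs`
#' column the centroid alone is classified.
#'
#' @param otus OTU tibble from [cluster_otus()].
#' @param ancestral An `ancestral_ref`.
#' @param panel Panel tibble.
#' @param params [classifier_params()].
#' @return Classification tibble keyed by `otu_id` with a `size` column.
#' @export
classify_otus <- function(otus, ancestral, panel,
                          params = classifier_params()) {
  if (nrow(otus) == 0) {
    out <- classify_sequences(tibble::tibble(id = character(),
                                             sequence = character()),
                              ancestral, panel, params)
    out$otu_id <- character(0)
    out$size <- integer(0)
    return(out)
  }
  candidates <- if ("candidate_seqs" %in% names(otus)) {
    otus$candidate_seqs
  } else {
    as.list(otus$centroid_sequence)
  }
  res <- purrr::map_dfr(seq_len(nrow(otus)), function(i) {
    cands <- candidates[[i]]
    calls <- classify_sequences(
      tibble::tibble(id = paste0(otus$otu_id[i], "|", seq_along(cands)),
                     sequence = cands),
      ancestral, panel, params
    )
    covered <- rowSums(as.matrix(
      calls[, grep("_status$", names(calls)), drop = FALSE]) != "uncovered")
    best <- order(-covered, -calls$score, seq_along(cands))[1]
    out <- calls[best, ]
    out$id <- otus$otu_id[i]
    out
  })
  res |>
    dplyr::rename(otu_id = "id") |>
    dplyr::mutate(size = otus$size[match(.data$otu_id, otus$otu_id)])
}
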
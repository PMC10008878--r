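# Mock-community construction and error-bearing amplicon read simulation.
#
# Emulates a defined control pool: equal amounts of amplicon DNA from a set
# of known AA2 genes plus a bacterial non-haem off-target, sequenced with
# substitution/indel errors, random 3' length trimming and occasional
# two-parent chimeras. Every read carries ground-truth labels so downstream
# stages are verifiable.

#' Build a mock community from a reference panel
#'
#' Default weights are equal (an equimolar pool). The member list is
#' deterministic given the inputs: the first `n_aa2` AA2-typed panel records
#' (gene types MnP/VP/LiP/GP) in panel order, plus the named off-targets.
#'
#' @param panel Panel tibble.
#' @param n_aa2 Number of AA2-typed members to include.
#' @param offtarget_ids Ids of non-AA2 members to include.
#' @param weights Optional positive weights (one per member, AA2 members
#'   first); normalized to sum to 1.
#' @param description Free-text description.
#' @return A `mock_community` tibble: panel columns plus `weight`.
#' @export
build_mock_community <- function(panel, n_aa2 = 10, offtarget_ids = character(),
                                 weights = NULL,
                                 description = "equimolar mock community") {
  aa2 <- dplyr::filter(panel, .data$gene_type %in% c("MnP", "VP", "LiP", "GP"))
  if (nrow(aa2) < n_aa2) {
    abort(sprintf("requested %d AA2 members but panel has only %d",
                  n_aa2, nrow(aa2)))
  }
  missing_ot <- setdiff(offtarget_ids, panel$id)
  if (length(missing_ot) > 0) {
    abort(paste0("off-target id(s) not in panel: ",
                 paste(missing_ot, collapse = ", ")))
  }
  members <- dplyr::bind_rows(aa2[seq_len(n_aa2), ],
                              dplyr::filter(panel, .data$id %in% offtarget_ids))
  if (is.null(weights)) weights <- rep(1, nrow(members))
  if (length(weights) != nrow(members) || any(weights <= 0)) {
    abort("weights must be positive, one per member")
  }
  members$weight <- weights / sum(weights)
  attr(members, "description") <- description
  class(members) <- c("mock_community", class(members))
  members
}

#' Read-simulation parameters
#'
#' Defaults reflect the mock-community control this pipeline is validated
#' against: 11,000 reads, 0.5 percent substitutions and 0.1 percent indels
#' per base, 1 percent chimeras, and 3' trimming to lengths drawn uniformly
#' from 200-568 nt (the trimmed amplicon range of the assay).
#'
#' @param total_reads Number of reads to simulate.
#' @param substitution_rate,indel_rate Per-base error rates in `[0, 1]`.
#' @param length_range Two integers, min/max read length applied by random
#'   3' trimming (a read shorter than the draw is kept whole).
#' @param chimera_rate Fraction of reads formed by joining two parents at a
#'   uniform breakpoint.
#' @param offtarget_fraction If not `NA`, the fraction of reads drawn from
#'   non-AA2 members (remaining reads drawn from AA2 members by weight);
#'   `NA` means draw all reads by community weight.
#' @param quality_profile `"constant"` (Q38 throughout) or `"decay3p"`
#'   (linear decay to Q10 over the final 50 bases, fodder for the quality
#'   trimmer).
#' @param seed Integer seed for the whole simulation.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(total_reads = 11000L, substitution_rate = 0.005,
                            indel_rate = 0.001, length_range = c(200L, 568L),
                            chimera_rate = 0.01, offtarget_fraction = NA_real_,
                            quality_profile = c("constant", "decay3p"),
                            seed = 1L) {
  quality_profile <- match.arg(quality_profile)
  rates <- c(substitution_rate, indel_rate, chimera_rate)
  stopifnot(all(rates >= 0 & rates <= 1), length(length_range) == 2,
            length_range[1] <= length_range[2], total_reads >= 0)
  if (!is.na(offtarget_fraction)) {
    stopifnot(offtarget_fraction >= 0, offtarget_fraction <= 1)
  }
  structure(list(total_reads = as.integer(total_reads),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 length_range = as.integer(length_range),
                 chimera_rate = chimera_rate,
                 offtarget_fraction = offtarget_fraction,
                 quality_profile = quality_profile,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate amplicon reads from a mock community
#'
#' Per read: the member of origin is drawn by weight (or by the
#' off-target/AA2 split when `offtarget_fraction` is set); one of the
#' member's amplicons is taken as the true fragment; with probability
#' `chimera_rate` a second parent is drawn and the two amplicons are joined
#' at a uniform breakpoint; substitutions and indels are applied per base;
#' the read is finally trimmed at the 3' end to a length drawn uniformly
#' from `length_range`. Identical inputs and seed give identical output.
#'
#' @param community `mock_community` tibble.
#' @param amplicons Product tibble from [in_silico_pcr()]/[nested_pcr()]
#'   whose `template_id` values are community member ids. Members without
#'   any amplicon are reported via a message and skipped.
#' @param params [read_sim_params()].
#' @return Tibble `read_id`, `sequence`, `quality`,
#'   `truth_member_id`, `truth_gene_type`, `is_chimera`.
#' @export
simulate_reads <- function(community, amplicons, params = read_sim_params()) {
  if (nrow(amplicons) == 0) abort("empty amplicon set")
  amp_by_member <- split(amplicons$sequence, amplicons$template_id)
  have <- community$id %in% names(amp_by_member)
  if (any(!have)) {
    message("members without amplicons skipped: ",
            paste(community$id[!have], collapse = ", "))
    community <- community[have, ]
  }
  if (nrow(community) == 0) abort("no community member has an amplicon")
  n <- params$total_reads
  if (n == 0) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(),
                          truth_member_id = character(),
                          truth_gene_type = character(),
                          is_chimera = logical()))
  }
  with_seed(params$seed, {
    w <- community$weight / sum(community$weight)
    is_ot <- community$gene_type == "non-AA2"
    if (!is.na(params$offtarget_fraction) && any(is_ot) && any(!is_ot)) {
      from_ot <- stats::runif(n) < params$offtarget_fraction
      member_idx <- integer(n)
      member_idx[from_ot] <- sample(which(is_ot), sum(from_ot), TRUE,
                                    prob = w[is_ot])
      member_idx[!from_ot] <- sample(which(!is_ot), sum(!from_ot), TRUE,
                                     prob = w[!is_ot])
    } else {
      member_idx <- sample(nrow(community), n, TRUE, prob = w)
    }
    chim <- stats::runif(n) < params$chimera_rate & nrow(community) > 1
    len_lo <- params$length_range[1]
    len_hi <- params$length_range[2]
    lens <- len_lo + sample.int(len_hi - len_lo + 1L, n, TRUE) - 1L

    draw_amplicon <- function(member) {
      amps <- amp_by_member[[community$id[member]]]
      amps[[sample.int(length(amps), 1)]]
    }
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- draw_amplicon(member_idx[i])
      if (chim[i]) {
        other <- sample(setdiff(seq_len(nrow(community)), member_idx[i]), 1)
        s2 <- draw_amplicon(other)
        bp <- sample.int(min(nchar(s), nchar(s2)) - 1L, 1)
        s <- paste0(substr(s, 1, bp), substr(s2, bp + 1, nchar(s2)))
      }
      s <- .apply_errors(s, params$substitution_rate, params$indel_rate)
      if (nchar(s) > lens[i]) s <- substr(s, 1, lens[i])
      seqs[i] <- s
    }
    quals <- .make_qualities(nchar(seqs), params$quality_profile)
    tibble::tibble(
      read_id = sprintf("read_%06d", seq_len(n)),
      sequence = seqs,
      quality = quals,
      truth_member_id = community$id[member_idx],
      truth_gene_type = community$gene_type[member_idx],
      is_chimera = chim
    )
  })
}

.apply_errors <- function(seq, sub_rate, indel_rate) {
  if (sub_rate <= 0 && indel_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (sub_rate > 0) {
    hit <- which(stats::runif(L) < sub_rate)
    if (length(hit) > 0) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, "")
    }
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(L) < indel_rate)
    if (length(hit) > 0) {
      ins <- stats::runif(length(hit)) < 0.5
      pieces <- as.list(chars)
      for (k in seq_along(hit)) {
        p <- hit[k]
        if (ins[k]) {
          pieces[[p]] <- c(sample(c("A", "C", "G", "T"), 1), pieces[[p]])
        } else {
          pieces[[p]] <- character(0)
        }
      }
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

.make_qualities <- function(lens, profile) {
  vapply(lens, function(L) {
    if (L == 0) return("")
    q <- rep(38L, L)
    if (profile == "decay3p" && L > 1) {
      k <- min(50L, L)
      tail_idx <- seq(L - k + 1, L)
      q[tail_idx] <- as.integer(round(seq(38, 10, length.out = k)))
    }
    intToUtf8(q + 33L)
  }, "")
}

#' Write simulated reads to FASTQ (Phred+33)
#' @param reads Read tibble from [simulate_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#' @param path FASTQ path (Phred+33).
#' @return Tibble `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  tibble::tibble(read_id = names(seqs),
                 sequence = unname(as.character(seqs)),
                 quality = unname(as.character(S4Vectors::mcols(seqs)$qualities)))
}

#' Write the ground-truth table for simulated reads
#' @param reads Read tibble from [simulate_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(reads, path) {
  readr::write_tsv(reads[, c("read_id", "truth_member_id", "truth_gene_type",
                             "is_chimera")], path, progress = FALSE)
  invisible(path)
}
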
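# Quality/length filtering, dereplication and greedy identity clustering.
#
# Filtering follows the stated rules of the assay: Q25 sliding-window
# quality trimming, removal of reads under 150 nt or containing ambiguous
# bases. OTUs are formed by de-novo greedy centroid clustering at 97%
# identity.

#' Read-filtering parameters
#'
#' @param quality_threshold Phred threshold for the 4-base sliding-window
#'   trimmer (default 25).
#' @param min_length Minimum retained read length in nt (default 150,
#'   boundary inclusive: a 150 nt read is kept).
#' @param max_ambiguous Maximum number of ambiguous bases tolerated
#'   (default 0).
#' @return A `filter_params` list.
#' @export
filter_params <- function(quality_threshold = 25L, min_length = 150L,
                          max_ambiguous = 0L) {
  stopifnot(quality_threshold >= 0, min_length >= 0, max_ambiguous >= 0)
  structure(list(quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length),
                 max_ambiguous = as.integer(max_ambiguous)),
            class = "filter_params")
}

#' Quality-trim reads at the 3' end
#'
#' Sliding-window rule: scanning 5' to 3', the read is cut at the first
#' position where the mean quality of the 4-base window starting there
#' (truncated at the read end) drops below the threshold; that position and
#' everything 3' of it is removed. Sequence and quality strings stay equal
#' length. An all-low-quality read becomes empty (and is then removed by the
#' length filter).
#'
#' @param reads Tibble with `sequence` and `quality` columns (Phred+33).
#' @param params [filter_params()].
#' @return The tibble with trimmed `sequence` and `quality`.
#' @export
quality_trim <- function(reads, params = filter_params()) {
  cut_at <- vapply(reads$quality, function(qs) {
    q <- utf8ToInt(qs) - 33L
    L <- length(q)
    if (L == 0) return(0L)
    cs <- cumsum(c(0L, q))
    ends <- pmin(seq_len(L) + 3L, L)
    means <- (cs[ends + 1L] - cs[seq_len(L)]) / (ends - seq_len(L) + 1L)
    bad <- which(means < params$quality_threshold)
    if (length(bad) == 0) L else bad[1] - 1L
  }, 0L, USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, cut_at)
  reads$quality <- substr(reads$quality, 1L, cut_at)
  reads
}

#' Filter reads by length and ambiguous bases
#'
#' A read is discarded iff its length is below `min_length` or it contains
#' more than `max_ambiguous` ambiguous (non-`A/C/G/T`) bases. Kept and
#' discarded partition the input.
#'
#' @param reads Read tibble with a `sequence` column.
#' @param params [filter_params()].
#' @return List with `kept` (the surviving rows) and `discarded` (the
#'   removed rows plus a `reason` column, `"length"` or `"ambiguous"`;
#'   length violations take precedence in the recorded reason).
#' @export
filter_reads <- function(reads, params = filter_params()) {
  len <- nchar(reads$sequence)
  n_ambig <- nchar(gsub("[ACGT]", "", toupper(reads$sequence)))
  too_short <- len < params$min_length
  too_ambig <- n_ambig > params$max_ambiguous
  drop <- too_short | too_ambig
  discarded <- reads[drop, , drop = FALSE]
  discarded$reason <- as.character(ifelse(too_short[drop], "length",
                                          "ambiguous"))
  list(kept = reads[!drop, , drop = FALSE], discarded = discarded)
}

#' Dereplicate reads into unique sequences
#'
#' Exact-sequence grouping. Output is ordered by (count descending, sequence
#' ascending); the representative id is the first read (input order) with
#' that sequence.
#'
#' @param reads Read tibble with `read_id` and `sequence`.
#' @return Tibble `sequence`, `count`, `representative_id`, `read_ids`
#'   (list-column).
#' @export
dereplicate <- function(reads) {
  reads |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = dplyr::n(),
                     representative_id = dplyr::first(.data$read_id),
                     read_ids = list(.data$read_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}

#' OTU clustering parameters
#'
#' Identity is computed on an ends-free global (overlap) alignment: internal
#' gaps count against identity, terminal overhangs (e.g. from 3' length
#' trimming) do not. Two denominators are available: alignment columns of
#' the overlapping region (default) or the shorter sequence length.
#'
#' @param identity_threshold Identity threshold in `(0, 1]` (default 0.97).
#' @param identity_definition `"alignment_columns"` or
#'   `"shorter_seq_length"`.
#' @param band Half-width of the alignment band (maximum cumulative indel
#'   drift tracked; default 24 nt, ample for amplicon reads).
#' @return A `clustering_params` list. The greedy input order is abundance
#'   descending, then length descending, then lexicographic; candidate
#'   centroids are tried in creation order.
#' @export
clustering_params <- function(identity_threshold = 0.97,
                              identity_definition = c("alignment_columns",
                                                      "shorter_seq_length"),
                              band = 24L) {
  identity_definition <- match.arg(identity_definition)
  stopifnot(identity_threshold > 0, identity_threshold <= 1, band >= 1)
  structure(list(identity_threshold = identity_threshold,
                 identity_definition = identity_definition,
                 band = as.integer(band),
                 tie_break = "abundance desc, length desc, lexicographic"),
            class = "clustering_params")
}

#' Pairwise sequence identity (ends-free alignment)
#'
#' Vectorized identity of each query against one reference under the
#' clustering identity model (banded ends-free global alignment; terminal
#' overhangs free, internal gaps counted).
#'
#' @param queries Character vector of sequences.
#' @param ref Single reference sequence.
#' @param definition `"alignment_columns"` or `"shorter_seq_length"`.
#' @param band Alignment band half-width.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
seq_identity <- function(queries, ref,
                         definition = c("alignment_columns",
                                        "shorter_seq_length"),
                         band = 24L) {
  definition <- match.arg(definition)
  overlap_identity_cpp(queries, ref,
                       band = as.integer(band),
                       definition = if (definition == "alignment_columns") 1L else 2L)
}

#' Greedy de-novo OTU clustering
#'
#' Unique sequences are visited in abundance order (count desc, length desc,
#' sequence asc). Each joins the earliest-created centroid with identity at
#' or above the threshold, otherwise founds a new OTU. A fast exact
#' substitution-only prefix check shortcuts the banded alignment for reads
#' without indels.
#'
#' @param uniques Dereplicated tibble from [dereplicate()].
#' @param params [clustering_params()].
#' @return Tibble `otu_id`, `centroid_sequence`, `size` (total reads),
#'   `n_uniques`, `member_ids` (list-column of read ids), `candidate_seqs`
#'   (list-column: typing candidates — the OTU consensus, its most
#'   abundant uniques and its longest unique),
#'   sorted by size descending (ties by centroid creation order).
#' @export
cluster_otus <- function(uniques, params = clustering_params()) {
  if (nrow(uniques) == 0) {
    return(tibble::tibble(otu_id = character(), centroid_sequence = character(),
                          size = integer(), n_uniques = integer(),
                          member_ids = list(), candidate_seqs = list()))
  }
  u <- dplyr::arrange(uniques, dplyr::desc(.data$count),
                      dplyr::desc(nchar(.data$sequence)), .data$sequence)
  n <- nrow(u)
  assign <- rep(NA_integer_, n)
  centroid_idx <- integer(0)
  remaining <- seq_len(n)
  t <- params$identity_threshold
  while (length(remaining) > 0) {
    c0 <- remaining[1]
    centroid_idx <- c(centroid_idx, c0)
    assign[c0] <- length(centroid_idx)
    rest <- remaining[-1]
    if (length(rest) == 0) break
    cen_seq <- u$sequence[c0]
    # shortcut: an exact shared-length prefix match has identity exactly 1
    # under either definition, so the alignment can be skipped
    mm <- prefix_mismatch_cpp(u$sequence[rest], cen_seq)
    hit <- mm == 0L
    need_aln <- which(!hit)
    if (length(need_aln) > 0) {
      ids <- seq_identity(u$sequence[rest[need_aln]], cen_seq,
                          definition = params$identity_definition,
                          band = params$band)
      hit[need_aln] <- ids >= t
    }
    assign[rest[hit]] <- length(centroid_idx)
    remaining <- rest[!hit]
  }
  otus <- tibble::tibble(cluster = seq_along(centroid_idx)) |>
    dplyr::mutate(
      centroid_sequence = u$sequence[centroid_idx],
      size = vapply(.data$cluster, function(k) {
        sum(u$count[assign == k])
      }, 0L),
      n_uniques = vapply(.data$cluster, function(k) sum(assign == k), 0L),
      member_ids = purrr::map(.data$cluster, function(k) {
        unlist(u$read_ids[assign == k], use.names = FALSE)
      }),
      # typing candidates: the OTU's positional consensus, its most
      # abundant uniques and its longest unique. 3' trimming can leave
      # every abundance-top unique truncated and leave the one clean
      # full-length molecule at count 1, so the consensus (weighted modal
      # base per position over the prefix-aligned uniques) recovers the
      # full-length error-free sequence whenever depth allows; downstream
      # typing picks the candidate whose alignment covers the most
      # framework residues
      candidate_seqs = purrr::map(.data$cluster, function(k) {
        seqs <- u$sequence[assign == k]
        counts <- u$count[assign == k]
        ord <- order(-counts, -nchar(seqs), seqs)
        top <- seqs[ord[seq_len(min(3, length(ord)))]]
        longest <- seqs[order(-nchar(seqs), -counts, seqs)][1]
        cons <- .otu_consensus(seqs, counts)
        unique(c(cons, top, longest))
      })
    ) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$cluster)
  otus$otu_id <- sprintf("OTU_%d", seq_len(nrow(otus)))
  otus[, c("otu_id", "centroid_sequence", "size", "n_uniques", "member_ids",
           "candidate_seqs")]
}

#' Expand OTU membership to a read-level map
#' @param otus OTU tibble from [cluster_otus()].
#' @return Tibble `read_id`, `otu_id`.
#' @export
otu_membership <- function(otus) {
  tidyr::unnest(otus[, c("otu_id", "member_ids")],
                cols = "member_ids") |>
    dplyr::transmute(read_id = .data$member_ids, otu_id = .data$otu_id)
}

#' Write OTU centroid sequences to FASTA
#'
#' Headers are `otu_id;size=N` and parse back losslessly.
#' @param otus OTU tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
pick_representatives <- function(otus, path) {
  seqs <- Biostrings::DNAStringSet(otus$centroid_sequence)
  names(seqs) <- sprintf("%s;size=%d", otus$otu_id, otus$size)
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Parse a centroid FASTA written by [pick_representatives()]
#' @param path FASTA path.
#' @return Tibble `otu_id`, `size`, `centroid_sequence`.
#' @export
read_representatives <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_match(names(seqs), "^(.*);size=(\\d+)$")
  tibble::tibble(otu_id = parts[, 2],
                 size = as.integer(parts[, 3]),
                 centroid_sequence = unname(as.character(seqs)))
}

#' Write OTU typing candidates to FASTA
#'
#' One record per candidate with headers `otu_id|rank`, so the typing stage
#' can weigh several abundant uniques per OTU rather than the centroid
#' alone.
#' @param otus OTU tibble from [cluster_otus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_otu_candidates <- function(otus, path) {
  recs <- tidyr::unnest(
    dplyr::mutate(otus[, c("otu_id", "candidate_seqs")],
                  candidate_seqs = purrr::map(.data$candidate_seqs,
                                              function(s) {
                                                tibble::tibble(rank = seq_along(s),
                                                               sequence = s)
                                              })),
    cols = "candidate_seqs")
  seqs <- Biostrings::DNAStringSet(recs$sequence)
  names(seqs) <- sprintf("%s|%d", recs$otu_id, recs$rank)
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Read OTU typing candidates written by [write_otu_candidates()]
#' @param path FASTA path.
#' @return Named list of character vectors, one per OTU in rank order.
#' @export
read_otu_candidates <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_match(names(seqs), "^(.*)\\|(\\d+)$")
  tbl <- tibble::tibble(otu_id = parts[, 2],
                        rank = as.integer(parts[, 3]),
                        sequence = unname(as.character(seqs))) |>
    dplyr::arrange(match(.data$otu_id, unique(.data$otu_id)), .data$rank)
  split(tbl$sequence, tbl$otu_id)[unique(tbl$otu_id)]
}

# Positional consensus over an OTU's unique sequences, weighted by read
# count. Reads are 3'-trimmed prefixes of their molecule, so ungapped
# positional voting aligns them exactly; indel-bearing reads contribute
# noise only downstream of their first indel and are outvoted. The
# consensus extends to the last position still covered by at least
# max(2, 5% of reads); an OTU too shallow for that yields NULL.
.otu_consensus <- function(seqs, counts) {
  size <- sum(counts)
  thr <- max(2, ceiling(0.05 * size))
  if (size < thr) return(NULL)
  maxL <- max(nchar(seqs))
  mat <- do.call(rbind, lapply(seqs, function(s) {
    c(strsplit(s, "", fixed = TRUE)[[1]], rep(NA, maxL - nchar(s)))
  }))
  coverage <- as.vector(counts %*% !is.na(mat))
  L <- max(c(0L, which(coverage >= thr)))
  if (L < 1) return(NULL)
  score <- vapply(c("A", "C", "G", "T"), function(b) {
    as.vector(counts %*% (!is.na(mat[, seq_len(L), drop = FALSE]) &
                            mat[, seq_len(L), drop = FALSE] == b))
  }, numeric(L))
  if (L == 1) score <- matrix(score, nrow = 1,
                              dimnames = list(NULL, c("A", "C", "G", "T")))
  paste(c("A", "C", "G", "T")[max.col(score, ties.method = "first")],
        collapse = "")
}
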
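# Shared fixtures and independent oracles.

# The synthetic study fixture (panel, ancestral reference, nested primers),
# generated once per test run.
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$fix)) {
    fixture_env$fix <- synthesize_reference_panel()
    tpl <- tibble::tibble(id = fixture_env$fix$panel$id,
                          sequence = fixture_env$fix$panel$nt_sequence)
    fixture_env$amplicons <- nested_pcr(tpl,
                                        fixture_env$fix$primers$round1_pairs,
                                        fixture_env$fix$primers$round2_pair)
  }
  list(fix = fixture_env$fix, amplicons = fixture_env$amplicons)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a DNA string at a given per-base substitution rate
mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  chars[hit] <- vapply(chars[hit],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       "")
  paste(chars, collapse = "")
}

# --- oracle: exhaustive position-by-position primer scan ------------------
# Checks every start on both strands with per-character IUPAC matching.
oracle_binding_sites <- function(primer_seq, template, params) {
  tpl <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  scan_one <- function(pseq, window_positions) {
    pc <- strsplit(pseq, "", fixed = TRUE)[[1]]
    L <- length(pc)
    out <- list()
    if (L > length(tpl)) return(out)
    for (i in seq_len(length(tpl) - L + 1)) {
      seg <- tpl[i:(i + L - 1)]
      mm <- !iupac_match(pc, seg)
      if (sum(mm) <= params$max_mismatches &&
          sum(mm[window_positions]) == 0) {
        out[[length(out) + 1]] <- c(start = i, mismatches = sum(mm))
      }
    }
    out
  }
  L <- nchar(primer_seq)
  w <- min(params$three_prime_window, L)
  plus <- scan_one(primer_seq, seq(L - w + 1, length.out = w))
  minus <- scan_one(revcomp(primer_seq), seq_len(w))
  mk <- function(lst, strand) {
    if (length(lst) == 0) {
      return(tibble::tibble(strand = character(), start = integer(),
                            end = integer(), mismatches = integer()))
    }
    m <- do.call(rbind, lst)
    tibble::tibble(strand = strand, start = as.integer(m[, "start"]),
                   end = as.integer(m[, "start"] + L - 1),
                   mismatches = as.integer(m[, "mismatches"]))
  }
  dplyr::arrange(dplyr::bind_rows(mk(plus, "+"), mk(minus, "-")),
                 strand, start)
}

# oracle: enumerate all convergent site pairs into products
oracle_pcr_products <- function(forward_seq, reverse_seq, template, params) {
  fs <- oracle_binding_sites(forward_seq, template, params)
  rs <- oracle_binding_sites(reverse_seq, template, params)
  out <- list()
  pair_up <- function(left, right, strand) {
    for (i in seq_len(nrow(left))) {
      for (j in seq_len(nrow(right))) {
        s <- left$start[i]; e <- right$end[j]
        len <- e - s + 1
        if (s <= right$start[j] && left$end[i] <= e &&
            len >= params$min_product && len <= params$max_product) {
          sq <- substr(template, s, e)
          if (strand == "-") sq <- revcomp(sq)
          out[[length(out) + 1]] <<- tibble::tibble(
            start = as.integer(s), end = as.integer(e), strand = strand,
            length = as.integer(len), sequence = sq)
        }
      }
    }
  }
  pair_up(dplyr::filter(fs, strand == "+"), dplyr::filter(rs, strand == "-"), "+")
  pair_up(dplyr::filter(rs, strand == "+"), dplyr::filter(fs, strand == "-"), "-")
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          sequence = character()))
  }
  dplyr::arrange(dplyr::distinct(res), strand, start, end)
}

# oracle: greedy clustering from a full all-pairs identity matrix
oracle_greedy_clusters <- function(uniques, params) {
  u <- dplyr::arrange(uniques, dplyr::desc(count),
                      dplyr::desc(nchar(sequence)), sequence)
  n <- nrow(u)
  idm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idm[, j] <- seq_identity(u$sequence, u$sequence[j],
                             definition = params$identity_definition,
                             band = params$band)
  }
  assign <- rep(NA_integer_, n)
  centroids <- integer(0)
  for (i in seq_len(n)) {
    hit <- NA_integer_
    for (k in seq_along(centroids)) {
      if (idm[i, centroids[k]] >= params$identity_threshold) { hit <- k; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    } else {
      assign[i] <- hit
    }
  }
  split(u$sequence, assign)
}

# independent statement of the typing rules for truth-table enumeration
oracle_label <- function(det, near_type, n_covered = 4L,
                         significant = TRUE, near_id = 1) {
  # det: named logical E37, E41, W171, D183 ("detected")
  if (!significant && near_id < 0.6) return("non-AA2")
  if (n_covered < 2) return("rest-AA2")
  if (det[["W171"]]) {
    if (det[["D183"]]) return("VP")
    if (det[["E37"]] && det[["E41"]]) return("VP")
    if (identical(near_type, "MnP")) return("VP")
    return("LiP")
  }
  if (sum(det[c("E37", "E41", "D183")]) >= 2) return("MnP")
  "rest-AA2"
}

make_calls <- function(statuses) {
  tibble::tibble(name = c("E37", "E41", "W171", "D183"),
                 status = statuses,
                 offset = ifelse(statuses == "present", 0L, NA_integer_))
}

expected_type_label <- c(MnP = "MnP", VP = "VP", LiP = "LiP",
                         GP = "rest-AA2", `non-AA2` = "non-AA2")

mutate_protein <- function(aa, rate) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  chars[hit] <- vapply(chars[hit],
                       function(a) sample(setdiff(AA_ALPHABET20, a), 1), "")
  paste(chars, collapse = "")
}
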
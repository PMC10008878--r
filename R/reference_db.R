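# Reference panel and ancestral-reference I/O.
#
# The panel is the curated databank of known class II peroxidase (AA2) coding
# sequences (plus deliberate off-targets such as bacterial non-haem
# peroxidases) with species/order/gene-type metadata. The ancestral reference
# is the lignin peroxidase protein whose numbering anchors the catalytic
# residue framework (E37, E41, W171, D183).

GENE_TYPES <- c("MnP", "VP", "LiP", "GP", "non-AA2", "unknown")
RESIDUE_ROLES <- c("Mn-binding", "substrate-Trp", "heme", "Ca-binding",
                   "disulfide")

#' Read an AA2 reference panel (FASTA + TSV metadata)
#'
#' Joins coding nucleotide sequences with their metadata by id. Every FASTA
#' record must have exactly one metadata row and vice versa; gene types must
#' come from the closed vocabulary `MnP, VP, LiP, GP, non-AA2, unknown`.
#'
#' @param fasta_path FASTA file of coding-orientation nucleotide sequences.
#' @param metadata_path Tab-separated metadata with header columns
#'   `id`, `species`, `tax_order`, `gene_type`, `source_note` and optionally
#'   `aa_sequence`.
#' @return A tibble with one row per panel member: `id`, `species`,
#'   `tax_order`, `gene_type`, `nt_sequence`, `aa_sequence` (may be `NA`),
#'   `source_note`.
#' @export
read_reference_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  required <- c("id", "species", "tax_order", "gene_type", "source_note")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$id)) {
    abort(paste0("duplicate metadata id(s): ",
                 paste(unique(meta$id[duplicated(meta$id)]), collapse = ", ")))
  }
  no_meta <- setdiff(ids, meta$id)
  if (length(no_meta) > 0) {
    abort(paste0("FASTA id(s) without metadata row: ",
                 paste(no_meta, collapse = ", ")))
  }
  no_seq <- setdiff(meta$id, ids)
  if (length(no_seq) > 0) {
    abort(paste0("metadata id(s) without FASTA record: ",
                 paste(no_seq, collapse = ", ")))
  }
  panel <- tibble::tibble(id = ids,
                          nt_sequence = toupper(as.character(seqs))) |>
    dplyr::left_join(meta, by = "id")
  if (!"aa_sequence" %in% names(panel)) panel$aa_sequence <- NA_character_
  panel <- panel[, c("id", "species", "tax_order", "gene_type",
                     "nt_sequence", "aa_sequence", "source_note")]
  validate_panel_fields(panel)
  panel
}

validate_panel_fields <- function(panel) {
  bad_type <- panel$id[!panel$gene_type %in% GENE_TYPES]
  if (length(bad_type) > 0) {
    abort(paste0("gene_type outside vocabulary {",
                 paste(GENE_TYPES, collapse = ", "), "} for id(s): ",
                 paste(bad_type, collapse = ", ")))
  }
  if (any(!nzchar(panel$nt_sequence))) {
    abort("empty nt_sequence in panel")
  }
  bad_nt <- panel$id[!.is_iupac_dna(panel$nt_sequence)]
  if (length(bad_nt) > 0) {
    abort(paste0("nt_sequence with non-IUPAC characters for id(s): ",
                 paste(bad_nt, collapse = ", ")))
  }
  has_aa <- !is.na(panel$aa_sequence)
  if (any(has_aa)) {
    ok <- !grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "*X]"),
                 panel$aa_sequence[has_aa])
    if (any(!ok)) {
      abort(paste0("aa_sequence with invalid characters for id(s): ",
                   paste(panel$id[has_aa][!ok], collapse = ", ")))
    }
  }
  invisible(panel)
}

#' Write an AA2 reference panel back to FASTA + TSV
#'
#' Inverse of [read_reference_panel()]; a write/read round trip reproduces
#' every field.
#'
#' @param panel Panel tibble.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_panel <- function(panel, fasta_path, metadata_path) {
  seqs <- Biostrings::DNAStringSet(panel$nt_sequence)
  names(seqs) <- panel$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80)
  meta_cols <- c("id", "species", "tax_order", "gene_type", "source_note",
                 "aa_sequence")
  readr::write_tsv(panel[, meta_cols], metadata_path, progress = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Default catalytic residue specification
#'
#' The four-residue framework on the ancestral lignin peroxidase numbering:
#' the Mn(II)-binding acidic triad E37, E41, D183 and the lignin-oxidizing
#' surface tryptophan W171. The tolerance of 1 admits residues found one
#' alignment column away (flagged as shifted).
#'
#' @return Tibble with columns `name`, `expected_aa`, `position`, `role`,
#'   `tolerance`.
#' @export
default_residue_specs <- function() {
  tibble::tibble(
    name = c("E37", "E41", "W171", "D183"),
    expected_aa = c("E", "E", "W", "D"),
    position = c(37L, 41L, 171L, 183L),
    role = c("Mn-binding", "Mn-binding", "substrate-Trp", "Mn-binding"),
    tolerance = 1L
  )
}

#' Construct an annotated ancestral reference
#'
#' @param id Identifier string.
#' @param aa_sequence Protein sequence (one-letter codes).
#' @param residues Residue-spec tibble as from [default_residue_specs()].
#' @param regions Optional conserved-region tibble with columns `label`,
#'   `start`, `end`, `motif` (1-based inclusive, motif length must equal the
#'   span).
#' @return An object of class `ancestral_ref`.
#' @export
ancestral_reference <- function(id, aa_sequence,
                                residues = default_residue_specs(),
                                regions = NULL) {
  aa_sequence <- toupper(aa_sequence)
  len <- nchar(aa_sequence)
  stopifnot(is.character(id), length(id) == 1, len > 0)
  residues <- tibble::as_tibble(residues)
  if (!all(residues$expected_aa %in% AA_ALPHABET20)) {
    abort("expected_aa must be a standard amino acid")
  }
  if (any(residues$position < 1 | residues$position > len)) {
    abort("residue position outside the ancestral sequence")
  }
  if (!all(residues$role %in% RESIDUE_ROLES)) {
    abort(paste0("residue role must be one of: ",
                 paste(RESIDUE_ROLES, collapse = ", ")))
  }
  found <- substring(aa_sequence, residues$position, residues$position)
  bad <- found != residues$expected_aa
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("expected %s at %d, found %s",
                  residues$expected_aa[i], residues$position[i], found[i]))
  }
  if (is.null(regions)) {
    regions <- tibble::tibble(label = character(), start = integer(),
                              end = integer(), motif = character())
  } else {
    regions <- tibble::as_tibble(regions)
    if (any(regions$start > regions$end) || any(regions$start < 1) ||
        any(regions$end > len)) {
      abort("conserved region outside the ancestral sequence")
    }
    if (any(nchar(regions$motif) != regions$end - regions$start + 1)) {
      abort("conserved region motif length must equal end - start + 1")
    }
  }
  structure(list(id = id, aa_sequence = aa_sequence,
                 residues = residues, regions = regions),
            class = "ancestral_ref")
}

#' Read the ancestral reference (FASTA + YAML annotation)
#'
#' The annotation file is YAML with a `residues` list (keys `name`, `aa`,
#' `pos`, `role`, `tol`) and an optional `regions` list (keys `label`,
#' `start`, `end`, `motif`). Positions are 1-based on the protein as given;
#' a mismatch between an expected residue and the sequence is a hard error.
#'
#' @param fasta_path Protein FASTA (first record used).
#' @param annotation_path YAML annotation path.
#' @return An `ancestral_ref` object.
#' @export
read_ancestral_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) < 1) abort("no sequence in ancestral FASTA")
  ann <- yaml::read_yaml(annotation_path)
  if (is.null(ann$residues)) abort("annotation lacks a 'residues' list")
  residues <- purrr::map_dfr(ann$residues, function(r) {
    tibble::tibble(name = r$name, expected_aa = r$aa,
                   position = as.integer(r$pos), role = r$role,
                   tolerance = as.integer(r$tol %||% 1L))
  })
  regions <- NULL
  if (!is.null(ann$regions)) {
    regions <- purrr::map_dfr(ann$regions, function(g) {
      tibble::tibble(label = g$label, start = as.integer(g$start),
                     end = as.integer(g$end), motif = g$motif)
    })
  }
  ancestral_reference(id = sub("\\s.*$", "", names(seqs)[1]),
                      aa_sequence = as.character(seqs[[1]]),
                      residues = residues, regions = regions)
}

#' Write an ancestral reference (FASTA + YAML annotation)
#' @param ancestral An `ancestral_ref` object.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ancestral_reference <- function(ancestral, fasta_path, annotation_path) {
  seqs <- Biostrings::AAStringSet(ancestral$aa_sequence)
  names(seqs) <- ancestral$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80)
  ann <- list(
    residues = purrr::pmap(ancestral$residues, function(name, expected_aa,
                                                        position, role,
                                                        tolerance) {
      list(name = name, aa = expected_aa, pos = position, role = role,
           tol = tolerance)
    }),
    regions = purrr::pmap(ancestral$regions, function(label, start, end,
                                                      motif) {
      list(label = label, start = start, end = end, motif = motif)
    })
  )
  yaml::write_yaml(ann, annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' @export
print.ancestral_ref <- function(x, ...) {
  cat("<ancestral_ref>", x$id, "-", nchar(x$aa_sequence), "aa\n")
  cat("residues:", paste(x$residues$name, collapse = ", "), "\n")
  if (nrow(x$regions) > 0)
    cat("conserved regions:", paste(x$regions$label, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ancestral_ref <- function(x, ...) x$residues

#' Summarize a reference panel
#'
#' Deterministic report: per-type counts, duplicate-sequence warnings and
#' alphabet violations. The panel itself is never modified.
#'
#' @param panel Panel tibble.
#' @return A `panel_validation` list with elements `counts` (tibble
#'   `gene_type`, `n`, zero-filled over the whole vocabulary), `duplicates`
#'   (tibble `nt_sequence`, `ids`) and `alphabet_violations` (tibble `id`,
#'   `field`).
#' @export
validate_panel <- function(panel) {
  counts <- tibble::tibble(gene_type = GENE_TYPES) |>
    dplyr::left_join(dplyr::count(panel, .data$gene_type), by = "gene_type") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  dup <- panel |>
    dplyr::group_by(.data$nt_sequence) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(ids = paste(.data$id, collapse = ","), .groups = "drop")
  viol <- panel |>
    dplyr::filter(!.is_iupac_dna(.data$nt_sequence)) |>
    dplyr::transmute(id = .data$id, field = "nt_sequence")
  structure(list(counts = counts, duplicates = dup,
                 alphabet_violations = viol),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("<panel_validation>\n")
  print(x$counts)
  cat(nrow(x$duplicates), "duplicate sequence group(s),",
      nrow(x$alphabet_violations), "alphabet violation(s)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
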
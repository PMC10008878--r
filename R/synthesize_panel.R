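# Synthetic AA2 reference panel, ancestral reference and primer set.
#
# The generator emulates the structure of a curated class II peroxidase
# databank well enough to exercise every pipeline stage: an ancestral lignin
# peroxidase protein carrying the catalytic framework (E37, E41, W171, D183),
# a panel of diverged family members whose framework residues encode their
# type (MnP / VP / LiP / GP), conserved primer-design regions shared by all
# members, and a bacterial-style non-haem off-target that amplifies with the
# same primers but is unrelated at the protein level.

# Low-degeneracy amino acids (<= 3 codons) keep designed primers usable.
.LOWDEG_AA <- c("M", "W", "F", "E", "D", "K", "N", "Y", "H", "Q", "C", "I")

# Fixed motif layout on the 250-aa ancestral protein (aa coordinates).
.MOTIF_LAYOUT <- list(
  outerF = list(start = 18L, motif = "MEWYHKFD"),
  innerF = list(start = 26L, motif = "WNEMFYKH"),
  innerR = list(start = 190L, motif = "HKYFMENW"),
  outerR = list(start = 198L, motif = "DFKHYWEM")
)

#' Synthesize an AA2 reference panel with its ancestral reference and primers
#'
#' Builds a fully synthetic but structurally realistic study fixture:
#' a 250-aa ancestral lignin peroxidase protein with `E37`, `E41`, `W171`,
#' `D183`; family members derived from it by amino-acid substitution
#' (catalytic positions set according to the member's gene type) and
#' independent synonymous codon choice; four conserved motif regions from
#' which nested primer pairs are designed by back-translation; and one
#' bacterial-style non-haem peroxidase off-target that carries the primer
#' binding sites out of frame, so it amplifies but encodes no AA2 protein.
#'
#' Defaults follow the mock-community design this pipeline is validated
#' against: 10 basidiomycete-style AA2 genes (4 MnP, 3 VP, 2 LiP, 1 GP) plus
#' the off-target, with pairwise amino-acid divergence of at least 5 percent.
#'
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @param n_mnp,n_vp,n_lip,n_gp Number of members per gene type.
#' @param include_offtarget Add the bacterial non-haem off-target member.
#' @param aa_divergence Per-position substitution probability applied to
#'   non-motif, non-catalytic positions of each member.
#' @return List with `panel` (tibble as from [read_reference_panel()]),
#'   `ancestral` (an `ancestral_ref`), `primers` (list with `round1_pairs`,
#'   a list of three forward/reverse pairs, and `round2_pair`).
#' @export
synthesize_reference_panel <- function(seed = 20230227, n_mnp = 4, n_vp = 3,
                                       n_lip = 2, n_gp = 1,
                                       include_offtarget = TRUE,
                                       aa_divergence = 0.08) {
  with_seed(seed, {
    len <- 250L
    specs <- default_residue_specs()
    motif_pos <- unlist(purrr::map(.MOTIF_LAYOUT, function(m) {
      seq(m$start, length.out = nchar(m$motif))
    }))
    # ancestral protein: random core, planted motifs, planted framework
    aa <- sample(AA_ALPHABET20, len, replace = TRUE)
    for (m in .MOTIF_LAYOUT) {
      aa[seq(m$start, length.out = nchar(m$motif))] <-
        strsplit(m$motif, "", fixed = TRUE)[[1]]
    }
    aa[specs$position] <- specs$expected_aa
    regions <- purrr::imap_dfr(.MOTIF_LAYOUT, function(m, nm) {
      tibble::tibble(label = nm, start = m$start,
                     end = m$start + nchar(m$motif) - 1L, motif = m$motif)
    })
    ancestral <- ancestral_reference("LiPH8-like-synthetic",
                                     paste(aa, collapse = ""),
                                     residues = specs, regions = regions)

    types <- c(rep("MnP", n_mnp), rep("VP", n_vp), rep("LiP", n_lip),
               rep("GP", n_gp))
    # framework residues by type: MnP has the acidic Mn-binding triad but no
    # surface Trp; VP has all four; LiP has the Trp without the triad; GP none.
    framework <- list(
      MnP = c(E37 = "E", E41 = "E", W171 = "A", D183 = "D"),
      VP  = c(E37 = "E", E41 = "E", W171 = "W", D183 = "D"),
      LiP = c(E37 = "A", E41 = "T", W171 = "W", D183 = "N"),
      GP  = c(E37 = "A", E41 = "T", W171 = "A", D183 = "N")
    )
    mutable <- setdiff(seq_len(len), c(motif_pos, specs$position))
    genera <- c("Mocknella", "Simulomyces", "Fabricata", "Synthetium",
                "Pseudogena", "Mockiporus", "Artificium", "Exemplaria",
                "Testudomyces", "Placebia")
    epithets <- c("alba", "rubra", "viridis", "minor", "major", "silvae",
                  "arenae", "collina", "montana", "litorea")
    orders <- c("Agaricales", "Polyporales", "Russulales", "Hymenochaetales",
                "Gomphales", "Geastrales", "Hysterangiales", "Trechisporales",
                "Agaricales", "Polyporales")

    make_members <- function() {
      purrr::map_dfr(seq_along(types), function(i) {
        maa <- aa
        flip <- mutable[stats::runif(length(mutable)) < aa_divergence]
        maa[flip] <- vapply(maa[flip], function(a) {
          sample(setdiff(AA_ALPHABET20, a), 1)
        }, "")
        maa[specs$position] <- framework[[types[i]]][specs$name]
        nt <- back_translate_random(paste(maa, collapse = ""))
        tibble::tibble(
          id = sprintf("%s%02d_%s", tolower(types[i]), i, "syn"),
          species = paste(genera[i], epithets[i]),
          tax_order = orders[i],
          gene_type = types[i],
          nt_sequence = nt,
          aa_sequence = paste(maa, collapse = ""),
          source_note = "synthetic AA2 family member"
        )
      })
    }
    # enforce pairwise amino-acid divergence >= 5% (regenerate if violated;
    # at the default mutation rate a violation is vanishingly rare)
    div_ok <- function(tbl) {
      mat <- do.call(rbind, strsplit(tbl$aa_sequence, "", fixed = TRUE))
      n <- nrow(mat)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (mean(mat[i, ] != mat[j, ]) < 0.05) return(FALSE)
      }
      TRUE
    }
    members <- make_members()
    tries <- 0L
    while (!div_ok(members)) {
      tries <- tries + 1L
      if (tries > 20L) abort("could not reach 5% pairwise divergence")
      members <- make_members()
    }

    panel <- members
    if (include_offtarget) {
      panel <- dplyr::bind_rows(panel, .synthesize_offtarget())
    }

    primers <- .design_panel_primers(ancestral)
    list(panel = panel, ancestral = ancestral, primers = primers)
  })
}

# Bacterial-style non-haem peroxidase off-target: random DNA carrying one
# concrete expansion of each primer site (inner and outer) at nested
# distances, deliberately out of frame relative to any AA2-like ORF.
.synthesize_offtarget <- function() {
  primers <- purrr::map(.MOTIF_LAYOUT, function(m) {
    design_degenerate_primer(m$motif, "forward")$sequence
  })
  pick <- function(iupac) {
    paste(vapply(strsplit(iupac, "", fixed = TRUE)[[1]], function(cd) {
      sample(iupac_expand(cd), 1)
    }, ""), collapse = "")
  }
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # layout (+ strand): pad, outerF, pad+1 (frameshift), innerF, core,
  # rc(innerR site), pad, rc(outerR site), pad
  # the reverse primers anneal to the minus strand, so their plus-strand
  # footprint is the motif coding sequence itself (one concrete expansion)
  site_outerF <- pick(primers$outerF)
  site_innerF <- pick(primers$innerF)
  site_innerR <- pick(primers$innerR)
  site_outerR <- pick(primers$outerR)
  seq <- paste0(rnd(30), site_outerF, rnd(10), site_innerF, rnd(430),
                site_innerR, rnd(10), site_outerR, rnd(30))
  tibble::tibble(
    id = "offt01_syn",
    species = "Rhizobium-like synthetic",
    tax_order = "Rhizobiales",
    gene_type = "non-AA2",
    nt_sequence = seq,
    aa_sequence = NA_character_,
    source_note = "synthetic bacterial non-haem peroxidase off-target"
  )
}

.design_panel_primers <- function(ancestral) {
  reg <- ancestral$regions
  get <- function(lbl, ori) {
    m <- reg[reg$label == lbl, ]
    design_degenerate_primer(m$motif, ori, name = paste0(lbl, "_", ori))
  }
  outerF <- get("outerF", "forward")
  innerF <- get("innerF", "forward")
  innerR <- get("innerR", "reverse")
  outerR <- get("outerR", "reverse")
  list(
    round1_pairs = list(
      list(forward = outerF, reverse = outerR),
      list(forward = outerF, reverse = innerR),
      list(forward = innerF, reverse = outerR)
    ),
    round2_pair = list(forward = innerF, reverse = innerR)
  )
}

#' Back-translate a protein with random synonymous codons
#'
#' Each amino acid is encoded by a codon drawn uniformly from its synonymous
#' set, so independently back-translated copies of similar proteins diverge
#' at the nucleotide level while degenerate primers designed from the
#' amino-acid motifs still match exactly.
#'
#' @param aa_sequence Protein string (standard amino acids).
#' @return DNA string.
#' @export
back_translate_random <- function(aa_sequence) {
  tab <- standard_codon_table()
  aas <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  paste(vapply(aas, function(a) {
    codons <- tab[[a]]
    if (is.null(codons)) abort(paste0("cannot back-translate residue: ", a))
    codons[sample.int(length(codons), 1)]
  }, ""), collapse = "")
}

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
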
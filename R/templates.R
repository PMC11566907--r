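# Built-in structure templates for the synthetic compound library.
# Each core is a kinase-inhibitor-like chemotype with two substitution
# slots {A} and {B}; substituents are enumerated combinatorially so that
# compounds sharing a core are structurally similar (meaningful Tanimoto
# clustering and non-degenerate MCS scaffolds), while cores are mutually
# dissimilar. Slots always follow an attachment atom, so a substituent's
# first atom is its attachment point; ring digits 1-2 are reserved for
# cores and 3 for substituents.

.st_cores <- c(
  benzamide            = "O=C(N{A})c1ccc({B})cc1",
  quinazolinamine      = "N({A})c1ncnc2cc({B})ccc12",
  diarylurea           = "O=C(N{A})Nc1ccc({B})cc1",
  aminopyrimidine      = "Nc1nc({A})cc({B})n1",
  arylsulfonamide      = "O=S(=O)(N{A})c1ccc({B})cc1",
  benzothiazole_amide  = "O=C({A})Nc1nc2cc({B})ccc2s1",
  nicotinamide         = "O=C(N{A})c1cncc({B})c1",
  oxadiazole           = "c1({A})nc({B})no1",
  quinolinamine        = "N({A})c1ccc2nc({B})ccc2c1",
  piperazine_pyrimidine = "N1({A})CCN(CC1)c2nc({B})ccn2",
  pyridine_carboxamide = "O=C(N{A})c1ccc({B})cn1",
  aryl_ether           = "O({A})c1ccc({B})cc1",
  phenylacetamide      = "O=C(N{A})Cc1ccc({B})cc1",
  aminothiazole        = "N({A})c1nc({B})cs1"
)

# substituent set shared by both slots; n_stereo is the number of
# undefined tetrahedral stereocenters each fragment contributes (fixed by
# construction: acyclic carbons with four distinct substituents, written
# without stereo annotations)
.st_substituents <- local({
  para_x <- c("F", "Cl", "Br", "C", "CC", "OC", "OCC", "C(F)(F)F",
              "N(C)C", "C#N", "O", "N")
  meta_x <- c("F", "Cl", "C", "OC", "C#N", "N")
  smi <- c(
    "",
    sprintf("c3ccc(%s)cc3", para_x),
    sprintf("c3cccc(%s)c3", meta_x),
    "c3ccccc3", "c3ccncc3", "c3cccnc3", "c3ncccn3", "c3ccco3", "c3cccs3",
    "C", "CC", "CCC", "CCCC", "C(C)C", "CC(C)C", "C(C)(C)C",
    "C3CC3", "C3CCC3", "C3CCCC3", "C3CCCCC3", "CC3CC3", "CC3CCCCC3",
    "CCO", "CCCO", "CCOC", "CCN(C)C", "CCC#N", "CC(=O)N(C)C", "CC(=O)OC",
    "CN(C)C", "COC",
    # one undefined stereocenter
    "C(C)CC", "C(C)CO", "C(O)CC", "CC(C)O", "C(C)c3ccccc3", "C(C)CCC",
    # two undefined stereocenters
    "C(C)C(C)O", "C(C)C(O)CC", "C(O)C(C)CC", "CC(C)C(C)O",
    # three undefined stereocenters
    "C(C)C(O)C(C)O", "C(C)C(C)C(C)O", "C(O)C(O)C(C)O"
  )
  n_stereo <- c(rep(0L, length(smi) - 13L), rep(1L, 6L), rep(2L, 4L), rep(3L, 3L))
  data.frame(smiles = smi, n_stereo = n_stereo, stringsAsFactors = FALSE)
})

# split each core template into the three constant pieces around {A},{B}
.st_core_pieces <- local({
  pieces <- lapply(.st_cores, function(s) {
    p1 <- strsplit(s, "{A}", fixed = TRUE)[[1]]
    p2 <- strsplit(p1[2], "{B}", fixed = TRUE)[[1]]
    c(p1[1], p2[1], p2[2])
  })
  do.call(rbind, pieces)
})

# assemble full SMILES for (core index, substituent A index, B index);
# vectorized over equal-length index vectors
.assemble_smiles <- function(core, a, b) {
  s <- paste0(.st_core_pieces[core, 1], .st_substituents$smiles[a],
              .st_core_pieces[core, 2], .st_substituents$smiles[b],
              .st_core_pieces[core, 3])
  gsub("()", "", s, fixed = TRUE)
}

# fragment molecular weights, cached on first use
.st_cache <- new.env(parent = emptyenv())

.fragment_mws <- function() {
  if (!is.null(.st_cache$sub_mw)) return(invisible(NULL))
  .st_cache$core_mw <- vapply(names(.st_cores), function(nm) {
    base <- gsub("()", "", gsub("\\{[AB]\\}", "", .st_cores[[nm]]), fixed = TRUE)
    mol_mw(base)
  }, numeric(1))
  .st_cache$sub_mw <- vapply(.st_substituents$smiles, function(s)
    if (nzchar(s)) mol_mw(s) else 0, numeric(1), USE.NAMES = FALSE)
  invisible(NULL)
}

# MW by fragment additivity: joining removes one H from each side
.assembled_mw <- function(core, a, b) {
  .fragment_mws()
  h2 <- 2 * .ST_MASS[["H"]]
  .st_cache$core_mw[core] +
    ifelse(nzchar(.st_substituents$smiles[a]), .st_cache$sub_mw[a] - h2, 0) +
    ifelse(nzchar(.st_substituents$smiles[b]), .st_cache$sub_mw[b] - h2, 0)
}
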
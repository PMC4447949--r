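# Residue and atom chemistry dictionaries used throughout the package.
# Heavy-atom only: deposited crystal structures at these resolutions carry no
# hydrogens, so donor/acceptor roles are assigned per atom name and residue.

.amino3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "SEP"
)

.dna_res <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U", "5CM", "5MC")

.water_res <- c("HOH", "WAT", "DOD", "H2O", "SOL")

#' Classify a residue name as protein, dna, water or other
#'
#' @param resid character vector of residue names (PDB conventions).
#' @return character vector over `{protein, dna, water, other}`.
#' @export
residue_kind <- function(resid) {
  resid <- toupper(trimws(resid))
  dplyr::case_when(
    resid %in% .amino3 ~ "protein",
    resid %in% .dna_res ~ "dna",
    resid %in% .water_res ~ "water",
    TRUE ~ "other"
  )
}

# One-letter base code for a nucleotide residue name ("" if not a base).
base_letter <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- rep("", length(resid))
  out[resid %in% c("DA", "A")] <- "A"
  out[resid %in% c("DC", "C")] <- "C"
  out[resid %in% c("DG", "G")] <- "G"
  out[resid %in% c("DT", "T")] <- "T"
  out[resid %in% c("DU", "U")] <- "U"
  out[resid %in% c("5CM", "5MC")] <- "C" # 5-methylcytosine pairs as C
  out
}

# van der Waals radii (Angstrom), element keyed. Bondi-style values; the
# default covers unparameterized elements with a warning upstream.
.vdw_radii <- c("C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80, "P" = 1.80,
                "H" = 1.20, "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98,
                "SE" = 1.90, "MG" = 1.73, "CA" = 2.31, "ZN" = 1.39,
                "NA" = 2.27, "K" = 2.75)

#' van der Waals radii for a vector of element symbols
#'
#' @param element character vector of element symbols.
#' @param default radius used for elements absent from the internal table.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, default = 1.70) {
  el <- toupper(trimws(element))
  r <- unname(.vdw_radii[el])
  if (anyNA(r)) {
    warn(paste0("unknown element(s) ", paste(unique(el[is.na(r)]), collapse = ", "),
                "; using default vdW radius ", default, " A"))
    r[is.na(r)] <- default
  }
  r
}

# Infer element symbol from a PDB atom name when the element column is blank.
guess_element <- function(elety) {
  nm <- gsub("[0-9'*\"]", "", toupper(trimws(elety)))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  out[two %in% c("CL", "BR", "ZN", "MG", "SE", "FE", "NA", "MN")] <- two[two %in%
    c("CL", "BR", "ZN", "MG", "SE", "FE", "NA", "MN")]
  out
}

# --- Hydrogen-bond donor/acceptor dictionary ---------------------------------
# role: "donor", "acceptor", or "both" (ambivalent). antecedent: covalently
# bonded heavy atom used for the base-antecedent-donor-acceptor angle proxy.
# Histidine ring nitrogens are treated as ambivalent (neutral tautomers).

.polar_protein <- tibble::tribble(
  ~resid, ~elety, ~role,      ~antecedent,
  "*",    "N",    "donor",    "CA",
  "*",    "O",    "acceptor", "C",
  "*",    "OXT",  "acceptor", "C",
  "SER",  "OG",   "both",     "CB",
  "THR",  "OG1",  "both",     "CB",
  "TYR",  "OH",   "both",     "CZ",
  "CYS",  "SG",   "donor",    "CB",
  "LYS",  "NZ",   "donor",    "CE",
  "ARG",  "NE",   "donor",    "CD",
  "ARG",  "NH1",  "donor",    "CZ",
  "ARG",  "NH2",  "donor",    "CZ",
  "HIS",  "ND1",  "both",     "CG",
  "HIS",  "NE2",  "both",     "CD2",
  "ASN",  "ND2",  "donor",    "CG",
  "ASN",  "OD1",  "acceptor", "CG",
  "GLN",  "NE2",  "donor",    "CD",
  "GLN",  "OE1",  "acceptor", "CD",
  "ASP",  "OD1",  "acceptor", "CG",
  "ASP",  "OD2",  "acceptor", "CG",
  "GLU",  "OE1",  "acceptor", "CD",
  "GLU",  "OE2",  "acceptor", "CD",
  "TRP",  "NE1",  "donor",    "CD1",
  "SEP",  "O1P",  "acceptor", "P",
  "SEP",  "O2P",  "acceptor", "P",
  "SEP",  "O3P",  "acceptor", "P"
)

.polar_dna_backbone <- tibble::tribble(
  ~elety, ~role,      ~antecedent,
  "OP1",  "acceptor", "P",
  "OP2",  "acceptor", "P",
  "O1P",  "acceptor", "P",
  "O2P",  "acceptor", "P",
  "O5'",  "acceptor", "P",
  "O3'",  "acceptor", "C3'",
  "O4'",  "acceptor", "C4'"
)

.polar_dna_base <- tibble::tribble(
  ~base, ~elety, ~role,      ~antecedent,
  "A",   "N1",   "acceptor", "C2",
  "A",   "N3",   "acceptor", "C2",
  "A",   "N7",   "acceptor", "C5",
  "A",   "N6",   "donor",    "C6",
  "G",   "N1",   "donor",    "C2",
  "G",   "N2",   "donor",    "C2",
  "G",   "N3",   "acceptor", "C2",
  "G",   "N7",   "acceptor", "C5",
  "G",   "O6",   "acceptor", "C6",
  "C",   "O2",   "acceptor", "C2",
  "C",   "N3",   "acceptor", "C2",
  "C",   "N4",   "donor",    "C4",
  "T",   "O2",   "acceptor", "C2",
  "T",   "N3",   "donor",    "C2",
  "T",   "O4",   "acceptor", "C4",
  "U",   "O2",   "acceptor", "C2",
  "U",   "N3",   "donor",    "C2",
  "U",   "O4",   "acceptor", "C4"
)

# Polar-atom table for a structure: one row per polar heavy atom with the
# donor/acceptor role and the antecedent atom name (NA when none applies).
polar_atoms <- function(structure) {
  at <- tibble::as_tibble(structure)
  at$.row <- seq_len(nrow(at))

  prot <- dplyr::filter(at, .data$kind == "protein")
  generic <- dplyr::inner_join(prot,
    dplyr::filter(.polar_protein, .data$resid == "*")[, -1],
    by = "elety")
  specific <- dplyr::inner_join(prot,
    dplyr::filter(.polar_protein, .data$resid != "*"),
    by = c("resid", "elety"))
  pr <- dplyr::bind_rows(generic, specific)

  dna <- dplyr::filter(at, .data$kind == "dna")
  bb <- dplyr::inner_join(dna, .polar_dna_backbone, by = "elety")
  dna$base <- base_letter(dna$resid)
  bs <- dplyr::inner_join(dna, .polar_dna_base, by = c("base", "elety"))
  bs$base <- NULL

  wat <- dplyr::filter(at, .data$kind == "water", .data$element == "O")
  if (nrow(wat) > 0) {
    wat$role <- "both"
    wat$antecedent <- NA_character_
  }

  out <- dplyr::bind_rows(pr, bb, bs, wat)
  dplyr::arrange(out, .data$.row)
}

# Charged-group dictionary for salt bridges (heavy atoms only). Histidine is
# treated as neutral by design decision, so it is not salt-bridge capable.
.charged_pos <- tibble::tribble(
  ~resid, ~elety,
  "LYS",  "NZ",
  "ARG",  "NE",
  "ARG",  "NH1",
  "ARG",  "NH2"
)

.charged_neg_protein <- tibble::tribble(
  ~resid, ~elety,
  "ASP",  "OD1",
  "ASP",  "OD2",
  "GLU",  "OE1",
  "GLU",  "OE2"
)

.charged_neg_dna <- c("OP1", "OP2", "O1P", "O2P")

charged_atoms <- function(structure) {
  at <- tibble::as_tibble(structure)
  at$.row <- seq_len(nrow(at))
  pos <- dplyr::inner_join(dplyr::filter(at, .data$kind == "protein"),
                           .charged_pos, by = c("resid", "elety"))
  if (nrow(pos) > 0) pos$charge <- "pos"
  negp <- dplyr::inner_join(dplyr::filter(at, .data$kind == "protein"),
                            .charged_neg_protein, by = c("resid", "elety"))
  if (nrow(negp) > 0) negp$charge <- "neg"
  negd <- dplyr::filter(at, .data$kind == "dna", .data$elety %in% .charged_neg_dna)
  if (nrow(negd) > 0) negd$charge <- "neg"
  dplyr::bind_rows(pos, negp, negd)
}

# --- DNA moiety classification ----------------------------------------------

.dna_backbone_atoms <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "O3'")
.dna_sugar_atoms <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'")

# Groove-face atom sets per base letter. Major-groove edge: purine N7/O6/N6,
# pyrimidine O4/N4/C5-methyl; minor-groove edge: purine N3/N2, pyrimidine O2.
.base_major <- list(
  A = c("N7", "N6", "C5", "C6"),
  G = c("N7", "O6", "C5", "C6"),
  C = c("N4", "C5", "C6", "C5M", "C7"),
  T = c("O4", "C5", "C6", "C5M", "C7"),
  U = c("O4", "C5", "C6")
)
.base_minor <- list(
  A = c("N3", "N1", "C2"),
  G = c("N3", "N2", "N1", "C2"),
  C = c("O2", "N3", "N1", "C2"),
  T = c("O2", "N3", "N1", "C2"),
  U = c("O2", "N3", "N1", "C2")
)

# Classify DNA atom names into phosphate_backbone / sugar / base_major /
# base_minor for a given base letter; "none" for non-DNA input.
dna_part_of <- function(elety, base) {
  n <- length(elety)
  out <- rep("none", n)
  out[elety %in% .dna_backbone_atoms] <- "phosphate_backbone"
  out[elety %in% .dna_sugar_atoms] <- "sugar"
  rest <- which(out == "none" & base != "")
  for (i in rest) {
    if (elety[i] %in% .base_major[[base[i]]]) {
      out[i] <- "base_major"
    } else if (elety[i] %in% .base_minor[[base[i]]]) {
      out[i] <- "base_minor"
    } else {
      out[i] <- "base_minor" # remaining ring atoms (e.g. N9, C4, C8) face edges
    }
  }
  out
}
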
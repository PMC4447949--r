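# Order-disorder profiling via normalized per-residue B-factors (apo vs
# DNA-bound comparison) and pairwise global sequence identity of protein
# domains.

#' Normalized per-residue B-factor profile
#'
#' Per-residue mean isotropic B over the chosen atom scope, then chain-mean
#' centred (normalized so the mean value is zero), so apo and complexed
#' chains refined at different overall scales are comparable.
#'
#' @param structure an `ets_structure` with B-factors.
#' @param chain chain identifier.
#' @param atom_scope `"all"` atoms of the residue or `"backbone"` (N, CA, C,
#'   O).
#' @param label profile label (defaults to the structure id).
#' @return tibble of class `ets_bprofile`: `resno`, `raw_b` (A^2),
#'   `norm_b` (mean-centred), `label`, `chain`.
#' @export
bfactor_profile <- function(structure, chain, atom_scope = c("all", "backbone"),
                            label = NULL) {
  atom_scope <- match.arg(atom_scope)
  at <- tibble::as_tibble(structure)
  at <- at[at$chain == chain, ]
  if (nrow(at) == 0) abort(paste0("chain not found: ", chain))
  if (atom_scope == "backbone") {
    at <- at[at$elety %in% c("N", "CA", "C", "O"), ]
  }
  prof <- at |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(raw_b = mean(.data$b), .groups = "drop") |>
    dplyr::arrange(.data$resno)
  prof$norm_b <- prof$raw_b - mean(prof$raw_b)
  prof$label <- label %||% attr(structure, "id")
  prof$chain <- chain
  class(prof) <- c("ets_bprofile", class(prof))
  prof
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (identity scoring: match +1, mismatch 0,
#' linear gap -1 by default) via Biostrings; percent identity counts
#' identical aligned columns over the alignment length excluding terminal
#' gaps.
#'
#' @param seq_a,seq_b amino-acid sequences (plain strings).
#' @param match,mismatch,gap scoring parameters.
#' @return one-row tibble of class `ets_identity`: `identity` (percent),
#'   `aligned_length`, `identities`, `score`, `gap_policy`.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("empty sequence")
  alphabet <- unique(c(strsplit(toupper(seq_a), "")[[1]],
                       strsplit(toupper(seq_b), "")[[1]]))
  mat <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    toupper(seq_a), toupper(seq_b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n <- length(a)
  # trim terminal gap columns
  lead <- 0L
  while (lead < n && (a[lead + 1] == "-" || b[lead + 1] == "-")) lead <- lead + 1L
  tail_ <- 0L
  while (tail_ < n - lead && (a[n - tail_] == "-" || b[n - tail_] == "-")) {
    tail_ <- tail_ + 1L
  }
  core <- seq.int(lead + 1L, n - tail_)
  ident <- sum(a[core] == b[core] & a[core] != "-")
  out <- tibble::tibble(
    identity = 100 * ident / length(core),
    aligned_length = length(core),
    identities = ident,
    score = Biostrings::score(aln),
    gap_policy = "terminal gaps excluded from denominator"
  )
  class(out) <- c("ets_identity", class(out))
  out
}

.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", SEP = "S", MSE = "M")

#' One-letter amino-acid sequence of a protein chain
#'
#' Reads the modelled residues of a chain in author-number order;
#' non-standard residues map through the internal dictionary (unknowns
#' become X).
#'
#' @param structure an `ets_structure`.
#' @param chain chain identifier.
#' @return single string.
#' @export
chain_sequence <- function(structure, chain) {
  res <- residues(structure)
  res <- res[res$chain == chain & res$kind == "protein", ]
  if (nrow(res) == 0) abort(paste0("no protein residues in chain ", chain))
  letters1 <- .aa321[toupper(res$resid)]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}
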
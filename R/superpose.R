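# Least-squares rigid superposition (Kabsch) and the default alpha-carbon
# pairing by author residue number.

#' Pair atoms of two structures by residue number and atom name
#'
#' The default pairing used for superposition: atoms with a given name
#' (alpha-carbons unless stated otherwise) in the shared author-numbered
#' residue range of one chain per structure.
#'
#' @param mobile,reference `ets_structure` objects.
#' @param elety atom name to pair on (default `"CA"`).
#' @param chain_mobile,chain_reference chains to pair; default: first chain
#'   containing `elety` atoms.
#' @return tibble with columns `i` (row in mobile) and `j` (row in reference).
#' @export
pair_atoms <- function(mobile, reference, elety = "CA",
                       chain_mobile = NULL, chain_reference = NULL) {
  pick <- function(s, ch) {
    at <- tibble::as_tibble(s)
    at$.row <- seq_len(nrow(at))
    at <- dplyr::filter(at, .data$elety == !!elety, .data$altloc %in% c("", "A"))
    if (is.null(ch)) ch <- at$chain[1]
    at <- dplyr::filter(at, .data$chain == ch)
    dplyr::distinct(at, .data$resno, .keep_all = TRUE)
  }
  am <- pick(mobile, chain_mobile)
  ar <- pick(reference, chain_reference)
  j <- match(am$resno, ar$resno)
  ok <- !is.na(j)
  tibble::tibble(i = am$.row[ok], j = ar$.row[j[ok]])
}

#' Optimal rigid superposition of two structures
#'
#' Computes the least-squares rotation and translation (Kabsch algorithm via
#' singular value decomposition) mapping the mobile atoms onto the reference,
#' and the RMSD over the pairing. The input structures are not modified; apply
#' the transform with [transform_structure()] or take `$mobile_transformed`.
#'
#' @param mobile,reference `ets_structure` objects.
#' @param pairing two-column table of paired atom row indices (mobile,
#'   reference); default from [pair_atoms()] on alpha-carbons.
#' @param elety atom name for the default pairing.
#' @return object of class `ets_superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_atoms`, and
#'   `mobile_transformed`.
#' @export
superpose <- function(mobile, reference, pairing = NULL, elety = "CA") {
  if (is.null(pairing)) pairing <- pair_atoms(mobile, reference, elety = elety)
  pairing <- tibble::as_tibble(pairing)
  if (nrow(pairing) < 3) {
    abort(sprintf("insufficient pairing: %d atom pairs (need >= 3)", nrow(pairing)))
  }
  P <- coords(mobile)[pairing[[1]], , drop = FALSE]
  Q <- coords(reference)[pairing[[2]], , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2) {
    abort("degenerate geometry: paired atoms are collinear")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  moved <- sweep(P %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  out <- list(rotation = R, translation = tr, rmsd = rmsd,
              n_atoms = nrow(pairing),
              mobile_transformed = transform_structure(mobile, R, tr))
  class(out) <- "ets_superposition"
  out
}

#' @export
print.ets_superposition <- function(x, ...) {
  cat(sprintf("<superposition>  rmsd %.3f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' @method tidy ets_superposition
#' @export
tidy.ets_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
                 rot_det = det(x$rotation),
                 tx = x$translation[1], ty = x$translation[2],
                 tz = x$translation[3])
}
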
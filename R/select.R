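# Atom selection. The selection surface is named arguments (chain, residue
# kind, residue-number ranges, atom-name sets, element) with an `invert` flag;
# selections are idempotent and compose by chaining.

#' Select atoms of a structure
#'
#' All supplied criteria are combined with AND; `invert = TRUE` negates the
#' combined predicate. An empty result is returned (with a warning), never an
#' error, so downstream code can flag it.
#'
#' @param structure an `ets_structure`.
#' @param chain chain identifier(s).
#' @param kind residue kind(s): `"protein"`, `"dna"`, `"water"`, `"other"`.
#' @param resno residue numbers (any integer vector, e.g. `334:426`).
#' @param elety atom name(s), e.g. `c("CA")` or `c("OP1","OP2")`.
#' @param element element symbol(s).
#' @param resid residue name(s), e.g. `"LYS"`.
#' @param invert negate the combined predicate.
#' @return an `ets_structure` with the matching atoms (possibly empty).
#' @export
str_select <- function(structure, chain = NULL, kind = NULL, resno = NULL,
                       elety = NULL, element = NULL, resid = NULL,
                       invert = FALSE) {
  if (!is_structure(structure)) abort("`structure` must be an ets_structure")
  if (!is.null(kind)) {
    bad <- setdiff(kind, c("protein", "dna", "water", "other"))
    if (length(bad) > 0) {
      abort(paste0("unknown residue kind: ", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(resno) && !is.numeric(resno)) {
    abort("`resno` must be numeric (residue numbers)")
  }
  at <- tibble::as_tibble(structure)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(kind)) keep <- keep & at$kind %in% kind
  if (!is.null(resno)) keep <- keep & at$resno %in% as.integer(resno)
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (!is.null(element)) keep <- keep & toupper(at$element) %in% toupper(element)
  if (!is.null(resid)) keep <- keep & toupper(at$resid) %in% toupper(resid)
  if (invert) keep <- !keep
  out <- at[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("selection matched no atoms")
  }
  new_structure(out, id = attr(structure, "id"), meta = attr(structure, "meta"),
                allow_empty = TRUE)
}
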
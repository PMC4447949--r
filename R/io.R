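# Reading and writing macromolecular coordinates. PDB files go through bio3d;
# mmCIF atom_site records are parsed directly (no installed R package reads
# mmCIF). Only model 1 is represented; waters get kind = "water"; author
# numbering is preserved.

#' Parse a PDB or mmCIF file into a structure
#'
#' All ATOM/HETATM records of model 1 are represented. By default only blank
#' or 'A' alternate locations are kept; `keep_all_altlocs = TRUE` retains all.
#'
#' @param path file path.
#' @param format `"auto"` (from extension, then content), `"pdb"` or `"mmcif"`.
#' @param keep_all_altlocs keep every alternate-location record.
#' @param id structure label; defaults to the file base name.
#' @return an [new_structure()] atom table.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_all_altlocs = FALSE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (grepl("^data_", first)) "mmcif" else "pdb"
    }
  }
  id <- id %||% tools::file_path_sans_ext(basename(path))
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  if (nrow(atoms) == 0) abort(paste0("empty structure: no atoms parsed from ", path))
  if (!keep_all_altlocs) {
    atoms <- dplyr::filter(atoms, .data$altloc %in% c("", "A"))
  }
  new_structure(atoms, id = id,
                meta = list(source = path, format = format, model = 1L))
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  tibble::tibble(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resid = a$resid,
    resno = a$resno,
    elety = a$elety,
    element = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                     NA_character_, trimws(a$elesy)),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b)
  )
}

# Minimal mmCIF atom_site reader: locates the atom_site loop, reads its
# column order, and splits data rows on whitespace (quoted tokens supported).
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tagged <- grep("^_atom_site\\.", lines)
  if (length(tagged) == 0) abort(paste0("mmCIF parse error in ", path,
                                        ": no _atom_site loop found"))
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagged]))
  body_start <- max(tagged) + 1L
  rows <- list()
  for (k in body_start:length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    tok <- scan(text = ln, what = character(), quiet = TRUE)
    if (length(tok) != length(tags)) {
      abort(sprintf("mmCIF parse error in %s at line %d: %d tokens for %d columns",
                    path, k, length(tok), length(tags)))
    }
    rows[[length(rows) + 1L]] <- tok
  }
  if (length(rows) == 0) abort(paste0("mmCIF parse error in ", path,
                                      ": atom_site loop has no data rows"))
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  getcol <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% tags) return(m[, nm])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(default, nrow(m))
  }
  model <- getcol("pdbx_PDB_model_num", default = "1")
  keep <- model == model[1]
  num <- function(v) suppressWarnings(as.numeric(v))
  blank_to <- function(v, to) ifelse(v %in% c(".", "?"), to, v)
  tibble::tibble(
    chain = blank_to(getcol("auth_asym_id", "label_asym_id"), "A")[keep],
    resid = blank_to(getcol("auth_comp_id", "label_comp_id"), "UNK")[keep],
    resno = as.integer(blank_to(getcol("auth_seq_id", "label_seq_id"), "0"))[keep],
    elety = blank_to(getcol("auth_atom_id", "label_atom_id"), "X")[keep],
    element = blank_to(getcol("type_symbol"), NA_character_)[keep],
    altloc = blank_to(getcol("label_alt_id", default = "."), "")[keep],
    x = num(getcol("Cartn_x"))[keep],
    y = num(getcol("Cartn_y"))[keep],
    z = num(getcol("Cartn_z"))[keep],
    o = num(blank_to(getcol("occupancy", default = "1"), "1"))[keep],
    b = num(blank_to(getcol("B_iso_or_equiv", default = "0"), "0"))[keep]
  )
}

#' Write a structure as a PDB file
#'
#' Coordinates are written at the PDB dialect's 3-decimal precision.
#'
#' @param structure an `ets_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- tibble::as_tibble(structure)
  ptype <- ifelse(at$kind %in% c("protein", "dna"), "ATOM", "HETATM")
  bio3d::write.pdb(
    file = path,
    type = ptype,
    xyz = as.numeric(t(coords(structure))),
    resno = at$resno,
    resid = at$resid,
    eleno = seq_len(nrow(at)),
    elety = at$elety,
    chain = at$chain,
    alt = ifelse(nzchar(at$altloc), at$altloc, ""),
    o = at$o,
    b = at$b,
    elesy = at$element
  )
  invisible(path)
}

#' Load a locally mirrored deposited structure
#'
#' Coordinate files from the Protein Data Bank are not redistributed with the
#' package; place downloaded copies (`<ACCESSION>.pdb` or `.cif`) in a local
#' directory and point `dir` (default: option `etsface.structure_dir`, falling
#' back to `inst/extdata/structures` inside the installed package) at it.
#'
#' @param accession 4-character PDB accession, e.g. `"4BNC"`.
#' @param dir directory containing the downloaded files.
#' @param ... passed to [read_structure()].
#' @return an `ets_structure`.
#' @export
read_deposited <- function(accession,
                           dir = getOption("etsface.structure_dir",
                                           system.file("extdata", "structures",
                                                       package = "etsface")),
                           ...) {
  acc <- toupper(accession)
  cand <- c(file.path(dir, paste0(acc, ".pdb")),
            file.path(dir, paste0(tolower(acc), ".pdb")),
            file.path(dir, paste0(acc, ".cif")),
            file.path(dir, paste0(tolower(acc), ".cif")))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0) {
    where <- if (is.null(dir) || !nzchar(dir)) {
      "a directory named by options(etsface.structure_dir = ...)"
    } else {
      dir
    }
    abort(paste0(
      "deposited entry ", acc, " not found locally; download it, e.g.\n",
      "  curl -O https://files.rcsb.org/download/", acc, ".pdb\n",
      "and place it under ", where
    ))
  }
  read_structure(hit[1], id = acc, ...)
}
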
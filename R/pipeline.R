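# Pipeline orchestration: a flat key/value configuration with centralized
# threshold defaults, and a runner that executes every analysis stage over a
# set of structures, writing per-structure JSON/TSV reports plus a summary
# table. Stage failures are recorded in the report; other stages proceed.

#' Pipeline configuration
#'
#' All numeric thresholds default to the values documented in the analysis
#' functions; every number in the report carries the threshold set used.
#'
#' @param inputs named character vector/list of structure paths (names become
#'   labels), or a list of `ets_structure` objects.
#' @param out_dir output directory (created if needed).
#' @param ... overrides for any default threshold (see
#'   [default_thresholds()]).
#' @return list of class `ets_config`.
#' @export
pipeline_config <- function(inputs = list(), out_dir = "etsface_report", ...) {
  thr <- utils::modifyList(default_thresholds(), list(...))
  out <- list(inputs = inputs, out_dir = out_dir, thresholds = thr)
  class(out) <- "ets_config"
  out
}

#' Default analysis thresholds
#' @return named list: every cutoff, radius and sampling density used by the
#'   analysis stages, with the package defaults.
#' @export
default_thresholds <- function() {
  list(
    hbond_cutoff = 3.5,
    salt_bridge_cutoff = 4.0,
    vdw_cutoff = 3.9,
    min_angle = 90,
    probe_radius = 1.4,
    sasa_points = 960L,
    area_convention = "half",
    water_cutoff = 3.5,
    match_radius = 1.0,
    bend_end_len = 4L,
    clash_overlap = 0.4,
    noise_sd = 0.02,
    seed = 1L
  )
}

#' Write / read a flat key=value configuration file
#'
#' The file form is one `key = value` pair per line; lists round-trip
#' losslessly for scalar values.
#'
#' @param config an `ets_config`.
#' @param path file path.
#' @return `read_config` returns an `ets_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  kv <- c(
    paste0("out_dir = ", config$out_dir),
    vapply(names(config$inputs), function(nm) {
      paste0("input.", nm, " = ", config$inputs[[nm]])
    }, character(1)),
    vapply(names(config$thresholds), function(nm) {
      paste0(nm, " = ", format(config$thresholds[[nm]], scientific = FALSE))
    }, character(1))
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  thr <- default_thresholds()
  inputs <- list()
  out_dir <- "etsface_report"
  for (i in seq_along(keys)) {
    k <- trimws(keys[i])
    v <- trimws(vals[i])
    if (k == "out_dir") {
      out_dir <- v
    } else if (startsWith(k, "input.")) {
      inputs[[sub("^input\\.", "", k)]] <- v
    } else if (k %in% names(thr)) {
      thr[[k]] <- if (k == "area_convention") v else as.numeric(v)
      if (k %in% c("sasa_points", "bend_end_len", "seed")) {
        thr[[k]] <- as.integer(thr[[k]])
      }
    }
  }
  cfg <- pipeline_config(inputs = inputs, out_dir = out_dir)
  cfg$thresholds <- thr
  cfg
}

#' Run the full interface-analysis pipeline
#'
#' For each input structure: protein-DNA contact map and base-pair span,
#' buried interface area, DNA shape versus the canonical B form, bridging
#' waters with hydrogen-assignment enumeration, and a normalized B-factor
#' profile. Individual stage failures are recorded and do not stop the other
#' stages. Writes `report.json` plus per-structure TSVs under
#' `config$out_dir`; deterministic for a fixed configuration (the seed is
#' part of it; no timestamps in the payload).
#'
#' @param config an `ets_config`.
#' @return the report (named list, one element per structure plus
#'   `thresholds`), invisibly; written to `report.json`.
#' @export
run_pipeline <- function(config) {
  thr <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(config$inputs)
  if (is.null(labels)) labels <- paste0("structure", seq_along(config$inputs))
  report <- list(thresholds = thr)
  for (k in seq_along(config$inputs)) {
    input <- config$inputs[[k]]
    lab <- labels[k]
    s <- if (is_structure(input)) input else read_structure(input)
    entry <- list(label = lab, n_atoms = nrow(s))
    stage <- function(name, expr) {
      res <- tryCatch(expr, error = function(e) {
        list(error = conditionMessage(e))
      })
      entry[[name]] <<- res
      res
    }

    has_dna <- any(tibble::as_tibble(s)$kind == "dna")
    has_protein <- any(tibble::as_tibble(s)$kind == "protein")
    pairs <- if (has_dna) {
      tryCatch(suppressWarnings(find_base_pairs(s)), error = function(e) NULL)
    } else NULL

    if (has_protein && has_dna) {
      stage("contacts", {
        cm <- contact_map(s, pairs = pairs,
                          cutoffs = list(hbond = thr$hbond_cutoff,
                                         salt_bridge = thr$salt_bridge_cutoff,
                                         vdw = thr$vdw_cutoff))
        utils::write.table(
          cm$contacts, file.path(config$out_dir, paste0(lab, "_contacts.tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
        list(n_hbond = sum(cm$contacts$kind == "hbond"),
             n_salt_bridge = sum(cm$contacts$kind == "salt_bridge"),
             n_vdw = sum(cm$contacts$kind == "vdw"),
             hbond_residues = unique(paste0(
               cm$contacts$resid1[cm$contacts$kind == "hbond"], "-",
               cm$contacts$resno1[cm$contacts$kind == "hbond"])),
             salt_bridge_residues = unique(paste0(
               cm$contacts$resid1[cm$contacts$kind == "salt_bridge"], "-",
               cm$contacts$resno1[cm$contacts$kind == "salt_bridge"])),
             span_bp = contacted_bp_span(s, pairs, max_dist = thr$vdw_cutoff))
      })
      stage("interface", {
        ia <- interface_area(s, list(kind = "protein"), list(kind = "dna"),
                             convention = thr$area_convention,
                             probe = thr$probe_radius,
                             n_points = thr$sasa_points)
        as.list(glance(ia))
      })
    }
    if (has_dna && !is.null(pairs) && nrow(pairs) >= 2 * thr$bend_end_len) {
      stage("dna_shape", {
        fr <- bp_frames(s, pairs)
        b <- bend_angle(fr, end_len = thr$bend_end_len)
        g <- groove_widths(s, pairs)
        utils::write.table(
          g, file.path(config$out_dir, paste0(lab, "_grooves.tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
        c(list(bend_deg = b$bend_angle), as.list(groove_extrema(g)))
      })
    }
    if (has_dna && has_protein) {
      stage("waters", {
        br <- suppressWarnings(find_bridging_waters(s, cutoff = thr$water_cutoff))
        res <- list(n_bridging = nrow(br))
        if (nrow(br) > 0 && nrow(br) <= 8) {
          g <- hbond_graph(s, br, cutoff = thr$water_cutoff, pairs = pairs)
          if (nrow(g$edges) <= 25) {
            asn <- enumerate_h_assignments(g)
            res$n_edges <- nrow(g$edges)
            res$n_assignments <- asn$n_solutions
          }
        }
        res
      })
    }
    if (has_protein) {
      stage("bprofile", {
        ch <- tibble::as_tibble(s) |>
          dplyr::filter(.data$kind == "protein") |>
          dplyr::pull(.data$chain)
        prof <- bfactor_profile(s, ch[1])
        utils::write.table(
          prof, file.path(config$out_dir, paste0(lab, "_bprofile.tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
        list(chain = ch[1], n_residues = nrow(prof),
             mean_norm_b = mean(prof$norm_b))
      })
    }
    report[[lab]] <- entry
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
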
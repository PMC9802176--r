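#' Read and write exchange-coupling tables
#'
#' Plain TSV dialect with header columns `pair` (e.g. `"1-2"`) and
#' `value_cm1`.
#'
#' @param path File path.
#' @return `read_j_table()` returns an [exchange_couplings];
#'   `write_j_table()` returns `path` invisibly.
#' @export
read_j_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    pair = readr::col_character(), value_cm1 = readr::col_double()
  ))
  exchange_couplings(stats::setNames(tab$value_cm1, tab$pair))
}

#' @rdname read_j_table
#' @param couplings An [exchange_couplings].
#' @export
write_j_table <- function(couplings, path) {
  readr::write_tsv(tibble::as_tibble(couplings), path)
  invisible(path)
}

#' Read a broken-symmetry energy table
#'
#' TSV with columns `signs` (e.g. `"++-+"`, spaces allowed), `energy`, and
#' `unit` (`"cm-1"` or `"hartree"`; hartree values are converted on input
#' at 219474.63 cm^-1 per hartree). Sign strings are canonicalized (first
#' sign up); duplicate configuration classes are an error.
#'
#' @param path File path.
#' @return A tibble with columns `signs`, `energy`, `unit` (`"cm-1"`),
#'   `source` (`"file"`), ready for [fit_exchange_couplings()].
#' @export
read_energy_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols())
  if (!all(c("signs", "energy") %in% names(tab))) {
    stop("energy table needs columns `signs` and `energy`: ", path,
      call. = FALSE
    )
  }
  unit <- if ("unit" %in% names(tab)) tab$unit else "cm-1"
  canon <- vapply(seq_len(nrow(tab)), function(i) {
    tryCatch(canonicalize_signs(tab$signs[i]), error = function(e) {
      stop("line ", i + 1, " of ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    })
  }, character(1))
  dup <- which(duplicated(canon))
  if (length(dup)) {
    stop("line ", dup[1] + 1, " of ", path, ": duplicate configuration class ",
      canon[dup[1]],
      call. = FALSE
    )
  }
  tibble::tibble(
    signs = canon,
    energy = convert_energy_cm1(tab$energy, unit),
    unit = "cm-1",
    source = "file"
  )
}

#' @rdname read_energy_table
#' @param energies Tibble with `signs`, `energy` and optional `unit`.
#' @export
write_energy_table <- function(energies, path) {
  cols <- intersect(c("signs", "energy", "unit"), names(energies))
  readr::write_tsv(energies[cols], path)
  invisible(path)
}

#' Write a simulated spectrum or level diagram to CSV
#'
#' Spectra are written with columns `field_G`, `absorption`, `derivative`;
#' level diagrams in wide form `field_G`, `E_1` ... `E_n` (cm^-1). Files
#' are written to a temporary name and renamed into place so a failed write
#' never leaves a partial file.
#'
#' @param spectrum An `epr_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  atomic_write(tibble::as_tibble(spectrum), path)
}

#' @rdname write_spectrum
#' @param diagram A `level_diagram`.
#' @export
write_level_diagram <- function(diagram, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(diagram),
    names_from = "level", values_from = "energy_cm1", names_prefix = "E_"
  )
  atomic_write(wide, path)
}

#' @rdname write_spectrum
#' @param ladder A `spin_ladder`.
#' @export
write_ladder <- function(ladder, path) {
  atomic_write(tibble::as_tibble(ladder), path)
}

atomic_write <- function(tab, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_csv(tab, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline: energies -> J -> ladder -> spectrum -> g
#'
#' Orchestrates the package stages from a single configuration list.
#' Couplings come from (in order of precedence) `config$couplings`, the
#' fixture named in `config$fixture`, a J-table at `config$j_table`, or a
#' fit to the energy table at `config$energies` (path or tibble). Stages
#' are any of `"fit"`, `"ladder"`, `"spectrum"`, `"g"`.
#'
#' @param config A list with elements: `stages` (character vector),
#'   `oxidation` (pattern string, default `"IV,IV,IV,III"`), one coupling
#'   source as above, optional `zfs` ([zfs_model], default total scheme
#'   D = -0.445 cm^-1, E/D = 0.25), optional `settings`
#'   ([spectrum_settings]), optional `out_dir` (artifacts written there
#'   when set), optional `seed`.
#' @return A list of class `pipeline_report`: `couplings`, `fit` (if run),
#'   `ladder`, `ground_spin`, `spectrum`, `g`, `files` (paths written) and
#'   `config` echo.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(
#'   fixture = "closed_W1OH_D170axis",
#'   stages = c("ladder", "spectrum", "g")
#' ))
#' rep$ground_spin # 5/2
#' }
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  stages <- config$stages %||% c("fit", "ladder", "spectrum", "g")
  bad <- setdiff(stages, c("fit", "ladder", "spectrum", "g"))
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  system <- spin_system(oxidation = config$oxidation %||% "IV,IV,IV,III")
  report <- list(config = config, files = character())

  fit <- NULL
  couplings <- NULL
  if (!is.null(config$couplings)) {
    couplings <- exchange_couplings(config$couplings)
  } else if (!is.null(config$fixture)) {
    fx <- fixture(config$fixture)
    couplings <- fx$couplings
    system <- fx$system
  } else if (!is.null(config$j_table)) {
    couplings <- read_j_table(config$j_table)
  } else if (!is.null(config$energies)) {
    energies <- config$energies
    if (is.character(energies)) energies <- read_energy_table(energies)
    if (!"fit" %in% stages) {
      stop("an energy table was supplied but \"fit\" is not among the stages",
        call. = FALSE
      )
    }
    fit <- fit_exchange_couplings(energies, system)
    couplings <- fit$couplings
  }
  if ("fit" %in% stages && is.null(fit) && is.null(couplings)) {
    stop("stage \"fit\" requires `energies`", call. = FALSE)
  }
  if (is.null(couplings)) {
    stop("no coupling source: give `couplings`, `fixture`, `j_table` or `energies`",
      call. = FALSE
    )
  }
  report$fit <- fit
  report$couplings <- couplings

  if (any(c("ladder", "spectrum", "g") %in% stages)) {
    if (is.null(couplings)) {
      stop("stages after \"fit\" need couplings", call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, obj, file) {
    if (is.null(out_dir)) {
      return(invisible(NULL))
    }
    path <- file.path(out_dir, file)
    writer(obj, path)
    report$files <<- c(report$files, path)
  }
  emit(write_j_table, couplings, "couplings.tsv")

  if ("ladder" %in% stages) {
    ladder <- spin_ladder(system, couplings)
    report$ladder <- ladder
    report$ground_spin <- ground_spin(ladder)
    emit(write_ladder, ladder, "ladder.csv")
  }
  if (any(c("spectrum", "g") %in% stages)) {
    zfs <- config$zfs %||% zfs_model("total", D = -0.445, E_over_D = 0.25)
    settings <- config$settings %||% spectrum_settings()
    spectrum <- powder_spectrum(system, couplings, zfs, settings)
    report$spectrum <- spectrum
    emit(write_spectrum, spectrum, "spectrum.csv")
    if ("g" %in% stages) report$g <- effective_g(spectrum)
  }
  if (!is.null(out_dir)) {
    sidecar <- list(
      package_version = as.character(utils::packageVersion("oecspin")),
      ground_spin = report$ground_spin,
      g = report$g,
      couplings = as.list(stats::setNames(
        as.numeric(couplings), names(couplings)
      )),
      stages = stages
    )
    path <- file.path(out_dir, "report.json")
    tmp <- paste0(path, ".tmp")
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, path)
    report$files <- c(report$files, path)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$ground_spin)) cat("  ground spin S =", format(x$ground_spin), "\n")
  if (!is.null(x$g)) cat("  effective g =", format(round(x$g, 3)), "\n")
  if (length(x$files)) cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
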
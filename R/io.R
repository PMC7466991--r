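# Scenario files (YAML), trajectory/tally serialisation and the fixture
# generator.

.sc_fields <- c("c_D", "c_B", "h", "timing", "targeted_trait", "brake_kind",
                "omega00", "d00", "beta00", "drive_ratio", "restoration",
                "K", "f_I", "N0B", "drive_intro", "dt", "thr", "tmax", "seed")

#' Read a scenario configuration file
#'
#' Scenario files are flat YAML whose keys are exactly the
#' [gdrive_scenario()] argument names (plus `N_star`, accepted as an
#' alternative to `K`).  Missing keys take the package defaults; unknown
#' keys are rejected with a message naming the key.  An empty file yields
#' the full default scenario.
#'
#' @param path path to a YAML scenario file.
#' @return A [gdrive_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("scenario file must be a YAML mapping",
                          call. = FALSE)
  allowed <- c(.sc_fields, "N_star")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         "; allowed keys are ", paste(allowed, collapse = ", "),
         call. = FALSE)
  do.call(gdrive_scenario, cfg)
}

#' Write a scenario configuration file
#'
#' Emits every resolved field in a fixed order (no timestamps), so
#' regenerated files are byte-identical and
#' `read_scenario(write_scenario(x))` reproduces `x`.
#'
#' @param scenario a [gdrive_scenario()].
#' @param path output path.
#' @param header optional character vector of comment lines (without the
#'   leading `#`) describing the scenario.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path, header = NULL) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  fields <- scenario[.sc_fields]
  fields <- fields[!vapply(fields, is.null, logical(1))]
  txt <- yaml::as.yaml(fields, precision = 15)
  lines <- character(0)
  if (!is.null(header)) lines <- paste("#", header)
  writeLines(c(lines, sub("\n$", "", txt)), path)
  invisible(path)
}

#' Generate the default scenario fixtures
#'
#' Writes the 24 factorial scenario configurations (conversion timing x
#' targeted trait x dominance x brake kind, at the default conversion
#' probabilities, standardisation ratio 1.1 and wild-type equilibrium
#' 10000) plus auxiliary two-allele classification configurations.  Each
#' file carries a comment header stating the constraints it satisfies.
#' Regeneration is byte-identical.
#'
#' @param out_dir writable output directory (created if needed).
#' @param tmax horizon written into the fixtures (default 2500, the
#'   outcome-classification horizon used for the sweep figures; the longer
#'   default of 25000 can be restored per file).
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, tmax = 2500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- gdrive_scenario(tmax = tmax)
  grid <- scenario_grid(base)
  paths <- character(0)
  for (id in names(grid)) {
    sc <- grid[[id]]
    if (inherits(sc, "try-error")) next
    tr <- scenario_traits(sc)
    hdr <- c(sprintf("scenario %s", id),
             sprintf("eradication standardisation: d_DD/(omega_DD beta_DD^2) = %g",
                     sc$drive_ratio),
             sprintf("wild-type equilibrium N* = %g",
                     wt_equilibrium_density(sc)),
             sprintf("brake homozygote %s = %g on trait %s",
                     sc$targeted_trait, tr[[sc$targeted_trait]]["BB"],
                     sc$targeted_trait))
    p <- file.path(out_dir, paste0(id, ".yaml"))
    write_scenario(sc, p, header = hdr)
    paths <- c(paths, p)
  }
  aux <- list(
    two_allele_threshold_independent = gdrive_scenario(
      c_D = 1, h = 0, timing = "germline", targeted_trait = "omega",
      tmax = tmax),
    two_allele_bistable = gdrive_scenario(
      c_D = 0.5, h = 1, timing = "germline", targeted_trait = "omega",
      tmax = tmax),
    two_allele_loss = gdrive_scenario(
      c_D = 0, h = 0.5, timing = "germline", targeted_trait = "omega",
      tmax = tmax))
  for (id in names(aux)) {
    p <- file.path(out_dir, paste0(id, ".yaml"))
    write_scenario(aux[[id]], p,
                   header = c(sprintf("auxiliary %s configuration", id),
                              "two-allele classification fixture",
                              "brake fields present but unused"))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a trajectory as CSV with a JSON event sidecar
#'
#' @param traj a `gdrive_trajectory`.
#' @param path CSV output path; the event log goes to `<path>.events.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "gdrive_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  ev <- attr(traj, "events")
  ev$outcome <- as.character(classify_outcome(traj))
  jsonlite::write_json(ev, paste0(path, ".events.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
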
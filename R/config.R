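# template of configuration keys, their types, and preset defaults
config_template <- function(preset = c("prokaryotes", "eukaryotes")) {
  preset <- match.arg(preset)
  list(
    mode = if (preset == "prokaryotes") "prokaryote" else "eukaryote",
    start_codons = "ATG",
    stop_codons = c("TAA", "TAG", "TGA"),
    min_orf_length = 9L,
    sd_window = 20L,
    sd_threshold = -3.0,
    asd_probe = "CCUCCU",
    level = "peptide",
    gap_open = 10,
    gap_extend = 1,
    min_coverage = 0.67,
    accept_ratio = 0.5,
    max_paths = 10L,
    upstream_length = 500L,
    scan_reverse = FALSE,
    output_dir = "uorfscout_output",
    seed = 1L
  )
}

config_types <- c(
  mode = "character", start_codons = "character", stop_codons = "character",
  min_orf_length = "numeric", sd_window = "numeric", sd_threshold = "numeric",
  asd_probe = "character", level = "character", gap_open = "numeric",
  gap_extend = "numeric", min_coverage = "numeric", accept_ratio = "numeric",
  max_paths = "numeric", upstream_length = "numeric", scan_reverse = "logical",
  output_dir = "character", seed = "numeric")

#' Load a run configuration
#'
#' Starts from a built-in preset (`"prokaryotes"` or `"eukaryotes"`,
#' mirroring the tool's two modes; the eukaryote preset disables
#' Shine-Dalgarno scanning) and overlays keys from an optional YAML file.
#' Defaults follow the tool's stated values: minimum ORF length 9 nt, SD
#' window 20 nt, upstream region length 500 nt. Unknown keys and type
#' mismatches are rejected by name.
#'
#' @param path optional path to a YAML key/value file.
#' @param preset `"prokaryotes"` (default) or `"eukaryotes"`.
#' @return An object of class `uorf_config`.
#' @export
load_config <- function(path = NULL, preset = c("prokaryotes", "eukaryotes")) {
  cfg <- config_template(match.arg(preset))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must contain key: value mappings")
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config key: ", unknown[1L])
    for (k in names(user)) {
      v <- user[[k]]
      want <- config_types[[k]]
      ok <- switch(want,
                   character = is.character(v),
                   numeric = is.numeric(v),
                   logical = is.logical(v))
      if (!ok) {
        stop("config key '", k, "' must be of type ", want, ", got ",
             class(v)[1L])
      }
      cfg[[k]] <- v
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$mode %in% c("prokaryote", "eukaryote")) {
    stop("config key 'mode' must be 'prokaryote' or 'eukaryote'")
  }
  if (!cfg$level %in% c("peptide", "nucleotide")) {
    stop("config key 'level' must be 'peptide' or 'nucleotide'")
  }
  cfg$min_orf_length <- as.integer(cfg$min_orf_length)
  cfg$sd_window <- as.integer(cfg$sd_window)
  cfg$max_paths <- as.integer(cfg$max_paths)
  cfg$upstream_length <- as.integer(cfg$upstream_length)
  cfg$seed <- as.integer(cfg$seed)
  # delegate range checks to the parameter constructors
  orf_params_from_config(cfg)
  conservation_params_from_config(cfg)
  scoring_scheme_from_config(cfg)
  structure(cfg, class = "uorf_config")
}

orf_params_from_config <- function(cfg) {
  orf_params(start_codons = cfg$start_codons, stop_codons = cfg$stop_codons,
             min_orf_length = cfg$min_orf_length, sd_window = cfg$sd_window,
             sd_threshold = cfg$sd_threshold, asd_probe = cfg$asd_probe)
}

conservation_params_from_config <- function(cfg) {
  conservation_params(min_coverage = cfg$min_coverage,
                      accept_ratio = cfg$accept_ratio,
                      max_paths = cfg$max_paths)
}

scoring_scheme_from_config <- function(cfg) {
  scoring_scheme(level = cfg$level, gap_open = cfg$gap_open,
                 gap_extend = cfg$gap_extend)
}

#' @export
print.uorf_config <- function(x, ...) {
  cat("uorfscout configuration:\n")
  for (k in names(x)) {
    cat(sprintf("  %-16s %s\n", k, paste(x[[k]], collapse = " ")))
  }
  invisible(x)
}
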
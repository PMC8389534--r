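## Run configuration shared by the command-line driver.

.CONFIG_DEFAULTS <- list(
  selection = "heavy",       # RMSD-matrix atom selection
  linkage = "average",       # clustering linkage
  superpose = TRUE,          # fit before pairwise RMSD
  contact_cutoff = 5.0,      # A
  hbond_cutoff = 3.5,        # A
  hbond_angle = 120,         # degrees
  saltbridge_cutoff = 4.0,   # A
  clash_cutoff = 2.0,        # A
  hotspot_threshold = 10.0,  # kcal/mol, strict >
  permutable_groups = list(),
  seed = 1L,
  out_dir = "."
)

#' Default run configuration
#'
#' The key-value configuration consumed by the command-line driver and
#' usable programmatically; see `inst/scripts/consensusdock.R`. Values in
#' a YAML file override the defaults; all cutoffs are in Angstrom, the
#' hotspot threshold in kcal/mol.
#'
#' @param path optional YAML file; `NULL` returns the defaults.
#' @return named list of configuration values.
#' @export
runConfig <- function(path = NULL) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package", call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(user)] <- user
  }
  for (k in c("contact_cutoff", "hbond_cutoff", "saltbridge_cutoff",
              "clash_cutoff"))
    if (cfg[[k]] <= 0) stop("config cutoff must be > 0: ", k, call. = FALSE)
  cfg
}

#' Stable hash of a run configuration
#'
#' MD5 of the deparsed configuration; embedded in reports so that any
#' output can be traced to the exact parameter set that produced it.
#'
#' @param cfg configuration list from [runConfig()].
#' @return hex digest string.
#' @export
configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[order(names(cfg))]), tf)
  unname(tools::md5sum(tf))
}
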
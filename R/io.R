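#' Load a reaction recipe from a YAML config
#'
#' The schema mirrors [reaction_recipe]: top-level keys `label`,
#' `temperature_K`, `buffer_mM`, `initial_mM` (named map of species),
#' `loadings` (list of maps with `enzyme`, `units_per_ml`, optional
#' `addition_time_h`) and optional `spikes` (list of maps with `time_h` and
#' `species_mM`).  Unknown keys and unknown species or enzyme names are
#' rejected with an informative message.
#'
#' @param path Path to a YAML file, e.g. one of the shipped fixtures under
#'   `system.file("extdata", package = "cascadekin")`.
#' @return A validated [reaction_recipe].
#' @examples
#' p <- system.file("extdata", "recipe_onepot_standard.yaml",
#'                  package = "cascadekin")
#' load_recipe_config(p)
#' @export
load_recipe_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || length(cfg) == 0)
    stop("empty recipe config: ", path)
  allowed <- c("label", "temperature_K", "buffer_mM", "initial_mM",
               "loadings", "spikes")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$initial_mM)) stop("config key 'initial_mM' is required")
  if (is.null(cfg$loadings)) stop("config key 'loadings' is required")
  initial <- unlist(cfg$initial_mM)
  if (any(initial < 0))
    stop("negative initial concentration for: ",
         paste(names(initial)[initial < 0], collapse = ", "))
  loadings <- lapply(cfg$loadings, function(l) {
    extra <- setdiff(names(l), c("enzyme", "units_per_ml", "addition_time_h"))
    if (length(extra) > 0)
      stop("unknown loading key(s): ", paste(extra, collapse = ", "))
    if (is.null(l$enzyme) || is.null(l$units_per_ml))
      stop("each loading needs 'enzyme' and 'units_per_ml'")
    loading(l$enzyme, l$units_per_ml,
            addition_time = if (is.null(l$addition_time_h)) 0 else l$addition_time_h)
  })
  spikes <- lapply(cfg$spikes, function(s) {
    extra <- setdiff(names(s), c("time_h", "species_mM"))
    if (length(extra) > 0)
      stop("unknown spike key(s): ", paste(extra, collapse = ", "))
    list(time = s$time_h, species = unlist(s$species_mM))
  })
  reaction_recipe(
    initial = do.call(species_vector, as.list(initial)),
    loadings = loadings, spikes = spikes,
    temperature = if (is.null(cfg$temperature_K)) 323 else cfg$temperature_K,
    buffer_mM = if (is.null(cfg$buffer_mM)) 100 else cfg$buffer_mM,
    label = if (is.null(cfg$label)) basename(path) else cfg$label)
}

#' Shipped reference recipes
#'
#' Convenience accessor for the recipe fixtures installed with the package:
#' `"onepot_standard"` (5 mM mannose, 5 mM NAD+, standard loadings
#' 0.2/0.1/0.4/11.6 U/ml), `"sequential"` (20 mM mannose, 20 mM NAD+,
#' timed additions at 1.5/16.5/17.5 h with a 10 mM NADH spike),
#' `"nmr"` (10 mM mannose, 10 mM NAD+, standard loadings; the real-time
#' NMR experiment) and `"scg"` / `"pure_mannose"` (hydrolysate-derived and
#' refined mannose at 14.57 and 13.9 mM with 3.75 mM NAD+).
#'
#' @param name Recipe name.
#' @return A [reaction_recipe].
#' @export
cascade_recipe <- function(name = c("onepot_standard", "sequential", "nmr",
                                    "scg", "pure_mannose")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0("recipe_", name, ".yaml"),
                   package = "cascadekin")
  if (!nzchar(f)) stop("recipe fixture not installed: ", name)
  load_recipe_config(f)
}

#' Write a time course to tidy CSV
#'
#' Long format with columns `time_h`, `species`, `value`, `kind`,
#' `replicate`; one row per species per time point.
#'
#' @param tc A [timecourse].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  df <- as.data.frame.timecourse(tc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  data.frame(
    time_h = rep(x$times, each = nrow(x$values)),
    species = rep(rownames(x$values), times = length(x$times)),
    value = as.vector(x$values),
    kind = x$kind,
    replicate = x$replicate,
    stringsAsFactors = FALSE)
}

#' Read a time course from tidy CSV
#'
#' Inverse of [write_timecourse_csv]; the round trip is lossless to full
#' float precision.  Species absent from the file are absent from the
#' returned matrix (partial observation, e.g. HPLC seeing only MAN and LA),
#' not filled with zeros.
#'
#' @param path CSV with columns `time_h`, `species`, `value`, `kind`,
#'   `replicate`.
#' @return A [timecourse] (or list of them if several replicates are
#'   present).
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "species", "value", "kind", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$species), CASCADE_SPECIES)
  if (length(bad) > 0)
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(CASCADE_SPECIES, collapse = ", "))
  one <- function(d) {
    times <- unique(d$time_h)  # file order; timecourse() rejects non-monotone grids
    sp <- intersect(CASCADE_SPECIES, unique(d$species))
    vals <- matrix(NA_real_, nrow = length(sp), ncol = length(times),
                   dimnames = list(sp, NULL))
    idx <- cbind(match(d$species, sp), match(d$time_h, times))
    vals[idx] <- d$value
    if (anyNA(vals)) stop("incomplete species x time grid in ", path)
    timecourse(times, vals, kind = unique(d$kind),
               replicate = unique(d$replicate))
  }
  reps <- unique(df$replicate)
  if (length(reps) == 1) return(one(df))
  lapply(split(df, df$replicate), one)
}
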
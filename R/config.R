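#' Pipeline configuration
#'
#' Every study constant is a named, defaulted key — never a hard-coded
#' literal inside a stage. Defaults are the values of the study design this
#' pipeline mirrors: a grass-lineage synonymous substitution rate
#' lambda = 6.5e-9 subs/site/year, Ka/Ks sliding windows of 150 bp stepped
#' by 9 bp, a >300 bp aligned-length floor for homolog calls, >=40%
#' identity for paralogs, 1,000 bootstrap replicates and 2,000 bp promoter
#' regions.
#'
#' @param lambda_rate Synonymous substitution rate, subs/site/year.
#' @param window_len Sliding-window length in bp (codon multiple advised).
#' @param window_step Sliding-window step in bp; must be <= `window_len`.
#' @param bbh_min_aln Minimum aligned length (bp, strict >) for homolog calls.
#' @param paralog_min_identity Minimum identity fraction (>=) for paralogs.
#' @param bootstrap_reps Bootstrap replicate count.
#' @param promoter_len Promoter length in bp upstream of the start codon.
#' @param rng_seed Integer seed governing all randomized stages.
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(rng_seed = 1)
#' cfg$lambda_rate
#' @export
pipeline_config <- function(lambda_rate = 6.5e-9,
                            window_len = 150L,
                            window_step = 9L,
                            bbh_min_aln = 300L,
                            paralog_min_identity = 0.40,
                            bootstrap_reps = 1000L,
                            promoter_len = 2000L,
                            rng_seed = 1L) {
  cfg <- list(lambda_rate = as.numeric(lambda_rate),
              window_len = as.integer(window_len),
              window_step = as.integer(window_step),
              bbh_min_aln = as.integer(bbh_min_aln),
              paralog_min_identity = as.numeric(paralog_min_identity),
              bootstrap_reps = as.integer(bootstrap_reps),
              promoter_len = as.integer(promoter_len),
              rng_seed = as.integer(rng_seed))
  if (any(vapply(cfg, function(v) !is.finite(v) || v <= 0, TRUE)) &&
      cfg$rng_seed != 0L)  # seed 0 allowed; everything else strictly positive
    if (any(unlist(cfg[names(cfg) != "rng_seed"]) <= 0))
      stop("all pipeline_config values must be positive", call. = FALSE)
  if (cfg$window_step > cfg$window_len)
    stop("window_step must be <= window_len", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a flat YAML configuration
#'
#' The file is a flat key: value mapping mirroring [pipeline_config()];
#' missing keys take their defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return [read_config()]: a `pipeline_config`; [write_config()]: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
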
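#' Configuration for the synthetic decoy-set generator
#'
#' The generator emulates the empirical setting of real loop decoy sets: each
#' scoring function is a noisy monotone function of model quality. Per decoy
#' j an RMSD is drawn from a folded, truncated normal; per function i the
#' score is the linear model
#' \deqn{score_{ij} = \alpha_i \cdot rmsd_j + \sigma_i \cdot \epsilon_{ij}}
#' with independent standard-normal noise. `alpha_i` sets the function's
#' informativeness (rank correlation with RMSD), `noise_sd_i` its noise.
#'
#' Defaults describe a moderately informative five-function setting: 300
#' decoys, all `alpha = 1`, `noise_sd = 0.5`, RMSD from |N(1.5, 1)| Angstrom
#' truncated (by rejection) to [0.05, 12].
#'
#' @param n_decoys Number of decoys (>= 2).
#' @param n_functions Number of scoring functions (>= 1).
#' @param alpha Informativeness weights, recycled to `n_functions`; all >= 0.
#' @param noise_sd Noise standard deviations, recycled; all >= 0.
#' @param rmsd_mu,rmsd_sd Parameters of the folded normal RMSD model.
#' @param rmsd_range Truncation interval for RMSD (Angstrom).
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_decoys = 300L, n_functions = 5L, alpha = 1,
                             noise_sd = 0.5, rmsd_mu = 1.5, rmsd_sd = 1,
                             rmsd_range = c(0.05, 12), seed = 1L) {
  if (n_decoys < 2) stop("n_decoys must be >= 2")
  if (n_functions < 1) stop("n_functions must be >= 1")
  alpha <- rep_len(alpha, n_functions)
  noise_sd <- rep_len(noise_sd, n_functions)
  if (any(alpha < 0) || any(noise_sd < 0))
    stop("alpha and noise_sd must be >= 0")
  if (rmsd_sd <= 0 || rmsd_range[1] < 0 || rmsd_range[2] <= rmsd_range[1])
    stop("invalid rmsd model parameters")
  structure(list(n_decoys = as.integer(n_decoys),
                 n_functions = as.integer(n_functions),
                 alpha = alpha, noise_sd = noise_sd,
                 rmsd_mu = rmsd_mu, rmsd_sd = rmsd_sd,
                 rmsd_range = rmsd_range, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Folded normal truncated by rejection; deterministic under the active RNG.
draw_rmsd <- function(n, mu, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- abs(stats::rnorm(n, mu, sd))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate one synthetic decoy set
#'
#' @param config A [synthetic_config()].
#' @param target_id Target identifier for the resulting table.
#' @return A `score_table` with RMSD, decoy ids `d0001`, `d0002`, ...;
#'   provenance attribute records the RNG kind and config.
#' @examples
#' tab <- generate_decoy_set(synthetic_config(n_decoys = 20, seed = 7))
#' range(tab$rmsd)
#' @export
generate_decoy_set <- function(config = synthetic_config(),
                               target_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_decoys; k <- config$n_functions
  rmsd <- draw_rmsd(n, config$rmsd_mu, config$rmsd_sd, config$rmsd_range)
  eps <- matrix(stats::rnorm(n * k), n, k)
  scores <- rmsd %*% t(config$alpha) +
    eps * matrix(config$noise_sd, n, k, byrow = TRUE)
  ids <- sprintf("d%04d", seq_len(n))
  out <- score_table(scores, decoy_ids = ids,
                     function_names = sprintf("s%d", seq_len(k)),
                     rmsd = rmsd, target_id = target_id)
  attr(out, "provenance") <- list(rng = "Mersenne-Twister/Inversion",
                                  config = unclass(config))
  out
}

#' Generate a multi-target synthetic benchmark on disk
#'
#' Writes `n_targets` score tables (target i uses seed `template$seed + i - 1`)
#' plus an evaluation manifest TSV with columns `target_id`, `path`, and
#' optional `group`.
#'
#' @param n_targets Number of targets (>= 1).
#' @param template A [synthetic_config()]; per-target seeds are derived from
#'   its seed.
#' @param dir Output directory (created if needed).
#' @param group_labels Optional vector recycled over targets (e.g. a loop
#'   length stand-in) recorded in the manifest.
#' @return The manifest as a data frame, invisibly; attribute
#'   `"manifest_path"` gives its location.
#' @export
generate_benchmark <- function(n_targets, template = synthetic_config(),
                               dir = ".", group_labels = NULL) {
  stopifnot(n_targets >= 1)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  rows <- lapply(seq_len(n_targets), function(i) {
    cfg <- template
    cfg$seed <- template$seed + i - 1L
    tid <- sprintf("synth%03d", i)
    tab <- generate_decoy_set(cfg, target_id = tid)
    p <- file.path(dir, paste0(tid, ".tsv"))
    write_score_table(tab, p)
    data.frame(target_id = tid, path = p, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(group_labels))
    manifest$group <- as.character(rep_len(group_labels, n_targets))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(manifest, "manifest_path") <- mp
  invisible(manifest)
}

#' Read an evaluation manifest
#'
#' @param path Manifest TSV with columns `target_id`, `path`, optional
#'   `group`. Relative table paths are resolved against the manifest's
#'   directory.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("target_id", "path") %in% names(m)))
    stop("manifest must have columns target_id and path")
  if (nrow(m) < 1) stop("manifest is empty")
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
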
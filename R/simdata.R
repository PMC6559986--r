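## Synthetic data with planted ground truth. All generators are pure
## functions of (parameters, seed).

#' Simulate a negative-binomial bulk count matrix with planted DE genes
#'
#' Counts follow `NB(mean = s_j * q_g * 2^(beta_g * x_gj), dispersion alpha)`
#' with variance `mu + alpha * mu^2` (DESeq parameterization). Per-sample
#' library factors `s_j` are log-uniform on `lib_size_range`; baseline
#' abundances `q_g` are log-normal (natural-log meanlog `baseline_meanlog`,
#' sdlog `baseline_sdlog`). A fraction `de_fraction` of genes gets
#' `beta_g = +/- lfc_magnitude` in one non-reference target group (the first
#' group is the reference); with two groups this is the classic two-condition
#' design. `dispersion = 0` degenerates to Poisson.
#'
#' @param n_genes number of genes (>= 1).
#' @param groups named integer vector, group label -> number of samples; all
#'   sizes >= 1. First element is the reference group.
#' @param de_fraction fraction of genes with a planted effect, in `[0, 1]`.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param lib_size_range range of the log-uniform library-size factors.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#'   parameters (natural log).
#' @param seed integer seed; identical parameters + seed give identical
#'   output.
#' @return list with `counts` (a [count_matrix()] whose `sample_meta` has a
#'   `condition` column) and `truth` (list: `de_genes`, per-gene `lfc`,
#'   per-gene target `group`, per-sample `group`, `seed`).
#' @export
simulate_counts <- function(n_genes = 2000,
                            groups = c(control = 10, tumor = 10),
                            de_fraction = 0.1, lfc_magnitude = 2,
                            dispersion = 0.2, lib_size_range = c(0.5, 2),
                            baseline_meanlog = 4, baseline_sdlog = 1.5,
                            seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector")
  if (any(groups < 1)) stop("every group needs >= 1 sample")
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(length(lib_size_range) == 2, all(lib_size_range > 0))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  genes <- sprintf("gene_%04d", seq_len(n_genes))
  cond <- rep(names(groups), times = groups)
  samples <- paste0(cond, "_", unlist(lapply(groups, seq_len)))

  q <- stats::rlnorm(n_genes, meanlog = baseline_meanlog,
                     sdlog = baseline_sdlog)
  s <- exp(stats::runif(length(samples), log(lib_size_range[1]),
                        log(lib_size_range[2])))

  n_de <- round(de_fraction * n_genes)
  if (n_de > 0 && length(groups) < 2)
    stop("planting DE genes needs >= 2 groups")
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
  lfc <- numeric(n_genes)
  target <- rep(NA_character_, n_genes)
  if (n_de > 0) {
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * lfc_magnitude
    tg <- if (length(groups) == 2) {
      rep(names(groups)[2], n_de)
    } else {
      sample(names(groups)[-1], n_de, replace = TRUE)
    }
    target[de_idx] <- tg
  }

  # per-gene mean matrix: baseline, multiplied by 2^lfc in the target group
  mu <- outer(q, s)
  if (n_de > 0) {
    for (i in de_idx) {
      j <- which(cond == target[i])
      mu[i, j] <- mu[i, j] * 2^lfc[i]
    }
  }
  counts <- if (dispersion == 0) {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = n_genes)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = n_genes)
  }
  dimnames(counts) <- list(genes, samples)
  cm <- count_matrix(counts,
                     sample_meta = data.frame(condition = cond,
                                              row.names = samples))
  truth <- list(de_genes = genes[de_idx],
                lfc = stats::setNames(lfc, genes),
                target_group = stats::setNames(target, genes),
                group = stats::setNames(cond, samples),
                lib_size = stats::setNames(s, samples),
                baseline = stats::setNames(q, genes),
                seed = seed)
  list(counts = cm, truth = truth)
}

#' Plant a state signature into selected samples
#'
#' Counts of the signature genes in the target samples are resampled from a
#' Poisson law whose mean is the observed count scaled by `2^effect_log2`,
#' keeping counts integral; all other entries are untouched.
#' `effect_log2 = 0` returns the input unchanged.
#'
#' @param x a [count_matrix()].
#' @param signature character vector of gene IDs, all present in `x`.
#' @param target_samples character vector of sample IDs, all present in `x`.
#' @param effect_log2 log2 effect size.
#' @param seed integer seed.
#' @return a [count_matrix()].
#' @export
inject_state_signature <- function(x, signature, target_samples, effect_log2,
                                   seed = 1) {
  stopifnot(inherits(x, "count_matrix"))
  miss_g <- setdiff(signature, rownames(x$counts))
  if (length(miss_g))
    stop("unknown gene(s): ", paste(miss_g, collapse = ", "))
  miss_s <- setdiff(target_samples, colnames(x$counts))
  if (length(miss_s))
    stop("unknown sample(s): ", paste(miss_s, collapse = ", "))
  if (effect_log2 == 0) return(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sub <- x$counts[signature, target_samples, drop = FALSE]
  new <- matrix(stats::rpois(length(sub), lambda = sub * 2^effect_log2),
                nrow = nrow(sub), dimnames = dimnames(sub))
  x$counts[signature, target_samples] <- new
  x
}

#' Construct a FACS intensity matrix container
#'
#' @param intensities cell x channel matrix of non-negative finite reals
#'   with unique cell row names and channel column names.
#' @param condition per-cell condition label.
#' @param transformed logical, whether intensities are on the arcsinh scale.
#' @param cofactor arcsinh cofactor used (NA when raw).
#' @return object of class `facs_matrix`.
#' @export
facs_matrix <- function(intensities, condition,
                        transformed = FALSE, cofactor = NA_real_) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities must have cell row names and channel column names")
  dup <- unique(rownames(intensities)[duplicated(rownames(intensities))])
  if (length(dup)) stop("duplicate cell IDs: ", paste(dup, collapse = ", "))
  if (any(!is.finite(intensities)) || (!transformed && any(intensities < 0)))
    stop("intensities must be finite and non-negative")
  if (length(condition) != nrow(intensities))
    stop("condition must have one label per cell")
  structure(list(intensities = intensities,
                 condition = stats::setNames(as.character(condition),
                                             rownames(intensities)),
                 transformed = transformed, cofactor = cofactor,
                 gated_channels = character()),
            class = "facs_matrix")
}

#' @export
print.facs_matrix <- function(x, ...) {
  cat(sprintf("facs_matrix: %d cells x %d channels (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$transformed) "arcsinh" else "raw"))
  print(table(x$condition))
  invisible(x)
}

#' Default four-cluster FACS population preset
#'
#' Emulates the four-condition slice-culture design read out by FACS on
#' purified astrocytes: both non-tumor conditions (with and without microglia
#' depletion) share one low-STAT3-P/low-KI67 mode; the tumor-injected,
#' microglia-depleted condition splits into two modes with moderately and
#' strongly increased KI67 but low STAT3-P; and the tumor-injected condition
#' with microglia present forms a single mode high in both STAT3-P and KI67.
#' Five populations over four condition labels, four separable clusters.
#' The moderate KI67 level sits midway between the low and high levels on
#' the arcsinh readout scale (cofactor 150), so the four modes are
#' resolvable; marker shifts span roughly 30-100x on the raw scale, typical
#' of a strong phospho/proliferation signal.
#'
#' @param n_cells cells per population.
#' @return list of population descriptors for [simulate_facs()].
#' @export
facs_preset <- function(n_cells = 150) {
  base <- list(`ZsGreen` = c(meanlog = 1.5, sdlog = 0.4),
               `HepaCAM` = c(meanlog = 6.0, sdlog = 0.4))
  pop <- function(label, stat3, ki67) {
    list(label = label, n_cells = n_cells,
         channels = c(base, list(`STAT3-P` = c(meanlog = stat3, sdlog = 0.4),
                                 `KI67` = c(meanlog = ki67, sdlog = 0.4))))
  }
  list(pop("control", 2.0, 2.0),
       pop("control_microglia_depleted", 2.0, 2.0),
       pop("tumor_microglia_depleted", 2.0, 5.3),
       pop("tumor_microglia_depleted", 2.0, 6.5),
       pop("tumor_microglia", 6.5, 6.5))
}

#' Simulate FACS intensities from log-normal populations
#'
#' Each cell is drawn from its population's per-channel log-normal law;
#' the population's condition label is recorded per cell.
#'
#' @param populations list of populations, each a list with `label`,
#'   `n_cells` and `channels` (named list of `c(meanlog =, sdlog =)`);
#'   default [facs_preset()].
#' @param seed integer seed.
#' @return a [facs_matrix()] on the raw intensity scale.
#' @export
simulate_facs <- function(populations = facs_preset(), seed = 1) {
  if (!length(populations)) stop("need >= 1 population")
  channels <- names(populations[[1]]$channels)
  for (p in populations) {
    if (p$n_cells < 1) stop("population '", p$label, "': n_cells must be >= 1")
    if (!identical(names(p$channels), channels))
      stop("all populations must share the same channel set")
    for (ch in channels)
      if (p$channels[[ch]][["sdlog"]] <= 0)
        stop("population '", p$label, "', channel '", ch,
             "': sdlog must be > 0")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mats <- lapply(populations, function(p) {
    m <- vapply(channels, function(ch) {
      stats::rlnorm(p$n_cells, meanlog = p$channels[[ch]][["meanlog"]],
                    sdlog = p$channels[[ch]][["sdlog"]])
    }, numeric(p$n_cells))
    if (p$n_cells == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, channels))
    m
  })
  inten <- do.call(rbind, mats)
  cond <- unlist(lapply(populations, function(p) rep(p$label, p$n_cells)))
  rownames(inten) <- sprintf("cell_%05d", seq_len(nrow(inten)))
  facs_matrix(inten, condition = cond)
}

## seed hygiene: generators must not disturb the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
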
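# Synthetic data generation: count tables, yield tables and barcoded
# reads with the statistical structure the analyses assume.
#
# The generative model mirrors the goodness-of-fit model: the true
# composition of a method is the expected composition distorted by
# per-taxon extraction efficiencies (cell lysis bias), replicate-level
# variation is Dirichlet with concentration theta, and sequencing is
# multinomial at a fixed depth. Block (experimenter) effects enter the
# yield model only: composition was found to be consistent across
# experimenters, so the count model deliberately carries no block term.

#' Simulation configuration
#'
#' @param community a [mock_community()].
#' @param methods named list: method label -> per-taxon extraction
#'   efficiency vector (recycled scalar allowed; values > 0, or 0 for a
#'   taxon the method cannot lyse at all).
#' @param theta replicate-level Dirichlet concentration (default 50, a
#'   moderate overdispersion typical of replicated amplicon data; `1e8`
#'   is effectively multinomial).
#' @param depth reads per replicate: a single value or one per replicate.
#'   Default 2000, a plausible per-sample depth for 454-era runs.
#' @param replicates_per_method default 8 (two experimenters x two days x
#'   two extractions).
#' @param experimenter_sd SD of the random experimenter block effect on
#'   the log-yield scale (default 0.2).
#' @param yield_model list with `mean_log_yield` (matrix, methods x
#'   samples, dimnames required) and `residual_sd`; `NULL` unless yields
#'   are simulated.
#' @param seed integer seed recorded in the config.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(community, methods, theta = 50, depth = 2000,
                              replicates_per_method = 8,
                              experimenter_sd = 0.2, yield_model = NULL,
                              seed = 1) {
  stopifnot(inherits(community, "mock_community"))
  if (!is.list(methods) || is.null(names(methods)) ||
      any(!nzchar(names(methods)))) {
    stop("methods must be a named list of efficiency vectors")
  }
  k <- nrow(community)
  methods <- lapply(methods, function(e) {
    e <- rep_len(as.numeric(e), k)
    if (anyNA(e) || any(e < 0)) stop("efficiencies must be non-negative")
    e
  })
  if (theta <= 0) stop("theta must be positive")
  if (any(depth < 1) || any(!is_whole(depth))) stop("depth must be a positive integer")
  if (replicates_per_method < 1) stop("need at least one replicate")
  if (experimenter_sd < 0) stop("experimenter_sd must be >= 0")
  if (!is.null(yield_model)) {
    if (is.null(yield_model$mean_log_yield) ||
        is.null(dimnames(yield_model$mean_log_yield))) {
      stop("yield_model$mean_log_yield must be a matrix with method/sample dimnames")
    }
    if (is.null(yield_model$residual_sd) || yield_model$residual_sd < 0) {
      stop("yield_model$residual_sd must be >= 0")
    }
  }
  structure(list(community = community, methods = methods, theta = theta,
                 depth = depth,
                 replicates_per_method = as.integer(replicates_per_method),
                 experimenter_sd = experimenter_sd,
                 yield_model = yield_model, seed = as.integer(seed)),
            class = "simulation_config")
}

# The 2 experimenters x 2 days layout cycled over replicates: two
# consecutive extractions per experimenter per day.
replicate_layout <- function(n, method) {
  i <- seq_len(n) - 1
  data.frame(replicate_id = sprintf("%s_r%d", method, i + 1),
             method = method,
             experimenter = c("expA", "expA", "expB", "expB")[(i %% 4) + 1],
             day = c("day1", "day2")[(i %/% 4) %% 2 + 1],
             stringsAsFactors = FALSE)
}

#' Simulate a count table for one method
#'
#' True composition `rho_i` is proportional to
#' `cell_fraction_i * copy_number_i * efficiency_i`; each replicate draws
#' proportions from `Dirichlet(theta * rho)` and counts from
#' `Multinomial(depth, p)`. Metadata follows the two-experimenter /
#' two-day layout. Bit-reproducible given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param method method label (must be in `config$methods`).
#' @return a [count_table()].
#' @export
simulate_counts <- function(config, method) {
  stopifnot(inherits(config, "simulation_config"))
  if (!method %in% names(config$methods)) {
    stop("unknown method: ", method)
  }
  eff <- config$methods[[method]]
  com <- config$community
  w <- com$cell_fraction * com$copy_number * eff
  if (all(w == 0)) stop("method ", method, " has zero efficiency everywhere")
  rho <- w / sum(w)
  names(rho) <- com$name
  n <- config$replicates_per_method
  depths <- rep_len(config$depth, n)
  # per-(config, method) substream so different methods give independent
  # draws under one config seed
  set.seed(config$seed + match(method, names(config$methods)) * 10007L)
  x <- rdm_counts(depths, rho, config$theta)
  meta <- replicate_layout(n, method)
  colnames(x) <- meta$replicate_id
  count_table(x, meta)
}

# Integer counts at exact total `depth` from a proportion vector
# (largest-remainder apportionment).
proportions_to_counts <- function(p, depth) {
  raw <- p * depth
  base <- floor(raw)
  short <- depth - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Reconstructed per-replicate count tables from published summaries
#'
#' The original per-replicate counts behind the packaged benchmark are
#' unpublished; this fixture *reconstructs* plausible count tables from
#' the published per-method means and SDs ([mock11_observed()]): each
#' replicate draws a truncated-normal jitter around the mean proportions
#' (SD = the printed SD), renormalizes onto the simplex, and converts to
#' integer counts at the requested depth (largest-remainder, columns sum
#' exactly to `depth`). Intended for qualitative reproduction of
#' benchmark-level conclusions, not as real data.
#'
#' @param depth reads per replicate (>= 100; default 2000).
#' @param n_replicates replicates per method (default 8).
#' @param seed integer seed (default 1).
#' @return named list of [count_table()]s, one per method.
#' @export
table4_fixture <- function(depth = 2000, n_replicates = 8, seed = 1) {
  if (depth < 100) stop("depth must be at least 100")
  obs <- mock11_observed()
  com <- mock11_community()
  methods <- sort(unique(obs$method))
  set.seed(seed)
  out <- lapply(methods, function(m) {
    sub <- obs[obs$method == m, ]
    sub <- sub[match(com$name, sub$taxon), ]
    mu <- sub$mean_pct / 100
    mu <- mu / sum(mu)
    sd <- sub$sd_pct / 100
    x <- matrix(0L, nrow(com), n_replicates,
                dimnames = list(com$name, NULL))
    for (j in seq_len(n_replicates)) {
      z <- rnorm(length(mu), mu, sd)
      while (any(z < 0)) {  # truncation at zero by redraw
        neg <- z < 0
        z[neg] <- rnorm(sum(neg), mu[neg], sd[neg])
      }
      x[, j] <- proportions_to_counts(z / sum(z), depth)
    }
    meta <- replicate_layout(n_replicates, m)
    colnames(x) <- meta$replicate_id
    count_table(x, meta)
  })
  names(out) <- methods
  out
}

#' Simulate a DNA-yield table
#'
#' Log concentration = `mean_log_yield[method, sample]` + random
#' experimenter block effect (`N(0, experimenter_sd)`, one draw per
#' experimenter) + residual noise (`N(0, residual_sd)`), over the
#' balanced 2 experimenters x 2 days x 2 replicates layout.
#'
#' @param config a [simulation_config()] with a `yield_model`.
#' @return a [yield_table()] (raw concentration scale).
#' @export
simulate_yields <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ym <- config$yield_model
  if (is.null(ym)) stop("config has no yield_model")
  mly <- ym$mean_log_yield
  methods <- rownames(mly)
  samples <- colnames(mly)
  set.seed(config$seed + 65537L)
  block_eff <- setNames(rnorm(2, 0, config$experimenter_sd),
                        c("expA", "expB"))
  rows <- list()
  for (m in methods) {
    for (s in samples) {
      for (e in c("expA", "expB")) {
        for (d in c("day1", "day2")) {
          for (r in 1:2) {
            lc <- mly[m, s] + block_eff[e] + rnorm(1, 0, ym$residual_sd)
            rows[[length(rows) + 1]] <- data.frame(
              method = m, sample = s,
              replicate = paste(e, d, r, sep = "_"),
              experimenter = e, day = d,
              concentration = exp(lc), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  yield_table(do.call(rbind, rows))
}

# One concrete expansion of an IUPAC string, degenerate positions chosen
# uniformly at random.
expand_iupac <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_EXPAND[[ch]]
    if (length(exp) == 1) exp else sample(exp, 1)
  }, character(1)), collapse = "")
}

mutate_bases <- function(seqn, error_rate) {
  if (error_rate <= 0) return(seqn)
  chars <- strsplit(seqn, "")[[1]]
  hit <- which(runif(length(chars)) < error_rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate barcoded amplicon reads from a count table
#'
#' Every count becomes one read: replicate barcode + 2-bp linker (`TC`) +
#' a randomly chosen concrete expansion of a degenerate forward primer +
#' the taxon's reference sequence, with independent per-base substitution
#' errors at `error_rate`. Ground truth (replicate and taxon) is kept in
#' the read id as `...|truth=<replicate>|taxon=<taxon>`.
#'
#' @param counts a [count_table()].
#' @param barcodes named barcode vector; names must cover the replicate
#'   ids of `counts`.
#' @param primers named IUPAC primer vector (default [primer_set_27f()]).
#' @param error_rate per-base substitution probability.
#' @param references optional named character vector of per-taxon
#'   template sequences; random 300-mers are generated when absent.
#' @param seed integer seed.
#' @return data frame with `id`, `sequence`, `quality` (uniform "I"),
#'   ready for [write_fastq()] / [filter_reads()].
#' @export
simulate_reads <- function(counts, barcodes, primers = primer_set_27f(),
                           error_rate = 0, references = NULL, seed = 1) {
  stopifnot(inherits(counts, "count_table"))
  reps <- colnames(counts$counts)
  if (!all(reps %in% names(barcodes))) {
    stop("barcodes must be named for every replicate id")
  }
  taxa <- rownames(counts$counts)
  set.seed(seed)
  if (is.null(references)) {
    # auto-generated templates avoid >6 bp homopolymers so pristine reads
    # pass the default QC policy by construction
    draw_ref <- function() {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
        if (longest_homopolymer(s) <= 6) return(s)
      }
    }
    references <- vapply(taxa, function(t) draw_ref(), character(1))
  }
  if (!all(taxa %in% names(references))) {
    stop("references must be named for every taxon")
  }
  total <- sum(counts$counts)
  ids <- character(total); seqs <- character(total)
  k <- 0L
  for (j in reps) {
    bc <- barcodes[[j]]
    for (t in taxa) {
      n <- counts$counts[t, j]
      if (n == 0) next
      for (r in seq_len(n)) {
        k <- k + 1L
        primer <- expand_iupac(primers[[sample(length(primers), 1)]])
        raw <- paste0(bc, "TC", primer, references[[t]])
        ids[k] <- sprintf("read%06d|truth=%s|taxon=%s", k, j, t)
        seqs[k] <- mutate_bases(raw, error_rate)
      }
    }
  }
  data.frame(id = ids, sequence = seqs,
             quality = vapply(nchar(seqs), function(n)
               paste(rep("I", n), collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}
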
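#' Configuration for the synthetic network generator
#'
#' The defaults describe a small but realistic testing world: 20
#' diseases, 15 miRNAs and 25 lncRNAs with sparse (8%) background
#' association rates, and 10 planted disease-lncRNA pairs that each
#' share 3 miRNA neighbors -- the co-neighborhood structure the scoring
#' method is designed to reward.
#'
#' @param n_diseases,n_mirnas,n_lncrnas positive layer sizes.
#' @param p_dm,p_ml background edge probabilities in `(0, 1)`.
#' @param n_gold number of planted disease-lncRNA pairs (`>= 0`, at most
#'   `n_diseases * n_lncrnas`).
#' @param signal_overlap miRNAs wired to both members of each planted
#'   pair (`0 <= signal_overlap <= n_mirnas`); 0 plants no signal, so
#'   gold pairs are indistinguishable from background.
#' @param seed integer seed; the same configuration always generates the
#'   same tables.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_diseases = 20L, n_mirnas = 15L,
                             n_lncrnas = 25L, p_dm = 0.08, p_ml = 0.08,
                             n_gold = 10L, signal_overlap = 3L, seed = 1L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_mirnas = as.integer(n_mirnas),
              n_lncrnas = as.integer(n_lncrnas),
              p_dm = p_dm, p_ml = p_ml,
              n_gold = as.integer(n_gold),
              signal_overlap = as.integer(signal_overlap),
              seed = as.integer(seed))
  with(cfg, {
    if (n_diseases < 1L || n_mirnas < 1L || n_lncrnas < 1L) {
      stop("layer sizes must be positive")
    }
    if (p_dm <= 0 || p_dm >= 1 || p_ml <= 0 || p_ml >= 1) {
      stop("edge probabilities must lie in (0, 1)")
    }
    if (n_gold < 0L || n_gold > n_diseases * n_lncrnas) {
      stop("n_gold must lie in [0, n_diseases * n_lncrnas]")
    }
    if (signal_overlap < 0L || signal_overlap > n_mirnas) {
      stop("signal_overlap must lie in [0, n_mirnas]")
    }
  })
  structure(cfg, class = "generator_config")
}

# Run code under a private RNG stream, restoring global RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.pad_names <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Generate synthetic association tables with an optional planted signal
#'
#' Draws two background bipartite edge sets (disease-miRNA and
#' miRNA-lncRNA) with independent Bernoulli edges, then plants `n_gold`
#' disease-lncRNA pairs by wiring `signal_overlap` randomly chosen
#' miRNAs to both members of each pair, creating the short
#' disease-miRNA-lncRNA paths and shared neighborhoods that raise both
#' the raw prediction score and the functional similarities.  The gold
#' table lists exactly the planted pairs.
#'
#' @param config a [generator_config()].
#' @return List of three `assoc_table`s: `dm` (disease-miRNA), `ml`
#'   (miRNA-lncRNA), `gold` (disease-lncRNA planted pairs; zero edges
#'   when `n_gold = 0`).
#' @export
generate_tables <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    ds <- .pad_names("disease", config$n_diseases)
    ms <- .pad_names("mir", config$n_mirnas)
    ls <- .pad_names("lnc", config$n_lncrnas)
    dm <- matrix(stats::runif(config$n_diseases * config$n_mirnas) < config$p_dm,
                 config$n_diseases, config$n_mirnas, dimnames = list(ds, ms))
    ml <- matrix(stats::runif(config$n_mirnas * config$n_lncrnas) < config$p_ml,
                 config$n_mirnas, config$n_lncrnas, dimnames = list(ms, ls))
    gold_cells <- sample(config$n_diseases * config$n_lncrnas, config$n_gold)
    gd <- ds[(gold_cells - 1L) %% config$n_diseases + 1L]
    gl <- ls[(gold_cells - 1L) %/% config$n_diseases + 1L]
    for (k in seq_len(config$n_gold)) {
      if (config$signal_overlap > 0L) {
        mm <- sample(config$n_mirnas, config$signal_overlap)
        dm[gd[k], mm] <- TRUE
        ml[mm, gl[k]] <- TRUE
      }
    }
    if (!any(dm) || !any(ml)) {
      stop("generated tables are empty; raise the edge probabilities ",
           "or plant a signal")
    }
    dm_idx <- which(dm, arr.ind = TRUE)
    ml_idx <- which(ml, arr.ind = TRUE)
    list(
      dm = assoc_table(
        data.frame(left = ds[dm_idx[, 1]], right = ms[dm_idx[, 2]]),
        "disease", "miRNA", "synthetic disease-miRNA"),
      ml = assoc_table(
        data.frame(left = ms[ml_idx[, 1]], right = ls[ml_idx[, 2]]),
        "miRNA", "lncRNA", "synthetic miRNA-lncRNA"),
      gold = assoc_table(
        data.frame(left = gd, right = gl,
                   stringsAsFactors = FALSE)[seq_len(config$n_gold), ,
                                             drop = FALSE],
        "disease", "lncRNA", "synthetic gold standard")
    )
  })
}

#' The fixed star worked-example network
#'
#' A 10-node network: one disease `D1` adjacent to four miRNAs `M1`-`M4`,
#' and five lncRNAs `L1`-`L5` each adjacent to at least one of those
#' miRNAs.  At radius 2 the distance correlation set of `D1` is all nine
#' other nodes; at radius 1 it is the four miRNAs.
#'
#' @return A `tripartite_network`.
#' @export
worked_example_network <- function() {
  dm <- assoc_table(
    data.frame(left = "D1", right = c("M1", "M2", "M3", "M4")),
    "disease", "miRNA", "worked example")
  ml <- assoc_table(
    data.frame(left = c("M1", "M1", "M2", "M3", "M4"),
               right = c("L1", "L2", "L3", "L4", "L5")),
    "miRNA", "lncRNA", "worked example")
  build_network(dm, ml)
}
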
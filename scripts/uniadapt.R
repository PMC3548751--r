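#!/usr/bin/env Rscript
# Command-line front end: `adapt` combines a literature CSV with an IPD CSV
# to estimate one adapted multivariable association; `simulate` runs a grid
# of Monte-Carlo scenarios. Thin wrapper over the uniadapt package.
#
#   Rscript scripts/uniadapt.R adapt --ipd ipd.csv --literature lit.csv \
#     --outcome y --predictor x1 --covariates x1,x2 \
#     --method improved-weak --pooling random --bootstrap 1000 --seed 1 \
#     --out adapted.csv [--format csv|json]
#
#   Rscript scripts/uniadapt.R simulate --config grid.yaml --out table.csv
#     (or flags: --n-ipd 100,1000 --n-lit 500 --sigma-h 0 --rho 0
#      --reps 500 --bootstrap 200 --seed 1
#      --methods no_meta,gs,improved_weak_prior)

suppressPackageStartupMessages({
  library(optparse)
  library(uniadapt)
})

usage_stop <- function() {
  stop("first argument must be `adapt` or `simulate`; see script header",
       call. = FALSE)
}

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) usage_stop()
mode <- argv[1]
rest <- argv[-1]
split_csv <- function(x) strsplit(x, ",")[[1]]

if (mode == "adapt") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--ipd", type = "character"),
    make_option("--literature", type = "character"),
    make_option("--outcome", type = "character", default = "y"),
    make_option("--predictor", type = "character"),
    make_option("--covariates", type = "character"),
    make_option("--method", type = "character", default = "improved-weak"),
    make_option("--pooling", type = "character", default = "random"),
    make_option("--c-weight", type = "double", default = 1, dest = "c_weight"),
    make_option("--bootstrap", type = "integer", default = 1000),
    make_option("--seed", type = "integer", default = 1),
    make_option("--ci-level", type = "double", default = 0.90,
                dest = "ci_level"),
    make_option("--out", type = "character", default = ""),
    make_option("--format", type = "character", default = "csv")
  )), args = rest)

  ipd <- read_ipd_csv(opts$ipd, outcome = opts$outcome)
  lit <- read_literature_csv(opts$literature)
  row <- adapt_association(
    ipd, lit, opts$outcome, opts$predictor, split_csv(opts$covariates),
    method = opts$method, pooling = opts$pooling, c_weight = opts$c_weight,
    n_bootstrap = opts$bootstrap, seed = opts$seed,
    conf.level = opts$ci_level
  )
  if (nzchar(opts$out)) {
    write_results(row, opts$out, format = opts$format,
                  config = opts[setdiff(names(opts), "help")],
                  seed = opts$seed)
    cat("wrote", opts$out, "\n")
  } else {
    print(as.data.frame(row), digits = 4)
  }
} else if (mode == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character", default = ""),
    make_option("--n-ipd", type = "character", default = "100",
                dest = "n_ipd"),
    make_option("--n-lit", type = "character", default = "500",
                dest = "n_lit"),
    make_option("--sigma-h", type = "character", default = "0",
                dest = "sigma_h"),
    make_option("--rho", type = "character", default = "0"),
    make_option("--reps", type = "integer", default = 500),
    make_option("--bootstrap", type = "integer", default = 1000),
    make_option("--seed", type = "integer", default = 1),
    make_option("--methods", type = "character",
                default = "no_meta,gs,improved_no_prior,improved_weak_prior"),
    make_option("--out", type = "character", default = "scenarios.csv"),
    make_option("--format", type = "character", default = "csv")
  )), args = rest)

  grid_opts <- list(
    n_ipd = as.numeric(split_csv(opts$n_ipd)),
    n_lit = as.numeric(split_csv(opts$n_lit)),
    sigma_h = as.numeric(split_csv(opts$sigma_h)),
    rho = as.numeric(split_csv(opts$rho))
  )
  if (nzchar(opts$config)) {
    cfg <- yaml::read_yaml(opts$config)
    for (k in names(grid_opts)) {
      if (!is.null(cfg[[k]])) grid_opts[[k]] <- as.numeric(cfg[[k]])
    }
    for (k in c("reps", "bootstrap", "seed")) {
      if (!is.null(cfg[[k]])) opts[[k]] <- as.integer(cfg[[k]])
    }
    if (!is.null(cfg$methods)) opts$methods <- paste(cfg$methods,
                                                     collapse = ",")
  }
  grid <- expand.grid(grid_opts)
  methods <- split_csv(opts$methods)

  tabs <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- scenario_config(
      n_ipd = grid$n_ipd[i], n_lit = grid$n_lit[i],
      sigma_h = grid$sigma_h[i], rho = grid$rho[i],
      n_reps = opts$reps, bootstrap_B = opts$bootstrap,
      seed = opts$seed + i - 1
    )
    message(sprintf("scenario %d/%d: N_I=%d N_L=%d sigma_h=%g rho=%g",
                    i, nrow(grid), cfg$n_ipd, cfg$n_lit, cfg$sigma_h,
                    cfg$rho))
    tidy(run_scenario(cfg, methods = methods))
  })
  out_tab <- dplyr::bind_rows(tabs)
  write_results(out_tab, opts$out, format = opts$format,
                config = list(reps = opts$reps, bootstrap = opts$bootstrap,
                              methods = opts$methods),
                seed = opts$seed)
  cat("wrote", opts$out, "\n")
} else {
  usage_stop()
}
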
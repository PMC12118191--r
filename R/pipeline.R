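# End-to-end orchestration (featurize -> pretreat -> train -> evaluate ->
# bep/qc) plus a small subcommand-style CLI. Run configuration is a JSON
# file; one global seed fans out deterministically to per-stage seeds.

#' Assemble a run configuration
#'
#' @param complexes_dir directory of PDB structures (one per complex) with
#'   matching \code{<id>_params.csv} sidecars.
#' @param labels_file kinetic dataset CSV (\code{complex_id,pkoff[,pkd]}).
#' @param out_dir output directory (created if absent).
#' @param ligand_name HETATM residue name of the ligand.
#' @param energetics an \code{\link{energetics_config}}.
#' @param pretreat a \code{\link{pretreat_config}}.
#' @param models list of \code{\link{regressor_spec}}s to compare.
#' @param split_period ranked-split period (default 5).
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(complexes_dir, labels_file, out_dir,
                       ligand_name = "LIG",
                       energetics = energetics_config(),
                       pretreat = pretreat_config(),
                       models = list(regressor_spec("PLSR"), regressor_spec("BNN")),
                       split_period = 5L, seed = 1L) {
  structure(list(complexes_dir = complexes_dir, labels_file = labels_file,
                 out_dir = out_dir, ligand_name = ligand_name,
                 energetics = energetics, pretreat = pretreat,
                 models = models, split_period = as.integer(split_period),
                 seed = as.integer(seed)),
            class = "run_config")
}

read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- lapply(raw$models %||% list(list(kind = "PLSR"), list(kind = "BNN")),
                   function(m) regressor_spec(m$kind,
                                              m$hyperparameters %||% list(),
                                              m$seed %||% (raw$seed %||% 1L)))
  run_config(
    complexes_dir = raw$complexes_dir, labels_file = raw$labels_file,
    out_dir = raw$out_dir %||% ".",
    ligand_name = raw$ligand_name %||% "LIG",
    energetics = do.call(energetics_config, raw$energetics %||% list()),
    pretreat = do.call(pretreat_config, raw$pretreat %||% list()),
    models = models,
    split_period = raw$split_period %||% 5L,
    seed = raw$seed %||% 1L
  )
}

#' Run the full modeling pipeline
#'
#' Reads every complex in \code{complexes_dir}, featurizes them into the
#' descriptor matrix, fits the shared pretreatment on the ranked training
#' split, compares all configured models (12 statistics each, including
#' leave-one-out cross-validation), fits the BEP relation when pKd values are
#' present, summarizes the labels, and writes everything plus a manifest
#' (config echo, input hashes, package version) under \code{out_dir}.
#' Rerunning with identical inputs and config reproduces the outputs.
#'
#' @param config a \code{\link{run_config}} or path to its JSON form.
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$labels_file)) {
    stopf("stage 'featurize': labels file '%s' does not exist", config$labels_file)
  }
  if (!dir.exists(config$complexes_dir)) {
    stopf("stage 'featurize': complexes directory '%s' does not exist",
          config$complexes_dir)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- featurize
  pdbs <- sort(list.files(config$complexes_dir, pattern = "\\.pdb$",
                          full.names = TRUE))
  if (!length(pdbs)) stopf("stage 'featurize': no .pdb files in '%s'", config$complexes_dir)
  complexes <- lapply(pdbs, function(p) {
    side <- sub("\\.pdb$", "_params.csv", p)
    if (!file.exists(side)) stopf("stage 'featurize': missing sidecar '%s'", side)
    read_complex(p, side, ligand_name = config$ligand_name)
  })
  X <- build_matrix(complexes, config$energetics)
  x_path <- file.path(config$out_dir, "X.csv")
  write_matrix(X, x_path)

  # --- labels, aligned to matrix rows
  dataset <- read_dataset(config$labels_file)
  m <- match(rownames(X), dataset$complex_id)
  if (anyNA(m)) {
    stopf("stage 'evaluate': labels missing for complex(es) %s",
          paste(rownames(X)[is.na(m)], collapse = ", "))
  }
  dataset <- dataset[m, , drop = FALSE]
  class(dataset) <- c("kinetic_dataset", "data.frame")

  # --- pretreat (training rows only) + model comparison
  pre_cfg <- config$pretreat
  models <- lapply(config$models, function(sp) {
    sp$seed <- stage_seed(config$seed, paste0("train:", sp$kind))
    sp
  })
  report <- compare_models(models, dataset, X, pre_cfg, config$split_period)
  report_path <- file.path(config$out_dir, "report.csv")
  rep_out <- as.data.frame(report)
  num <- vapply(rep_out, is.numeric, logical(1))
  rep_out[num] <- lapply(rep_out[num], function(v) sprintf("%.3f", v))
  write.csv(rep_out, report_path, row.names = FALSE, quote = FALSE)

  fp <- pretreat_fit(X[attr(report, "split")$train_indices, , drop = FALSE], pre_cfg)
  fitted_path <- file.path(config$out_dir, "pretreatment.json")
  save_pretreatment(fp, fitted_path)

  # --- dataset diagnostics
  qc <- list(label_summary = label_summary(dataset))
  if ("pkd" %in% names(dataset) && sum(is.finite(dataset$pkd)) >= 3) {
    bep <- bep_fit(dataset)
    qc$bep <- unclass(bep)
  }
  qc_path <- file.path(config$out_dir, "qc.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA)

  # --- manifest
  manifest <- list(
    package_version = as.character(utils::packageVersion("koffkit")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = list(ligand_name = config$ligand_name,
                  split_period = config$split_period,
                  energetics = unclass(config$energetics),
                  pretreat = unclass(config$pretreat),
                  models = lapply(models, unclass)),
    inputs = as.list(tools::md5sum(c(pdbs, config$labels_file)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(X = X, dataset = dataset, report = report, qc = qc,
                 paths = c(X = x_path, report = report_path, qc = qc_path,
                           pretreatment = fitted_path, manifest = manifest_path)))
}

#' Serialize / restore a fitted pretreatment as JSON
#'
#' @param fitted a \code{\link{pretreat_fit}} result.
#' @param path JSON file path.
#' @return \code{load_pretreatment} returns the restored
#'   \code{fitted_pretreatment}.
#' @export
save_pretreatment <- function(fitted, path) {
  out <- unclass(fitted)
  out$config <- unclass(out$config)
  out$pca_loadings <- as.data.frame(out$pca_loadings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_pretreatment
#' @export
load_pretreatment <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$config <- structure(raw$config, class = "pretreat_config")
  raw$pca_loadings <- as.matrix(raw$pca_loadings)
  dimnames(raw$pca_loadings) <- NULL
  raw$retained_columns <- as.integer(raw$retained_columns)
  structure(raw, class = "fitted_pretreatment")
}

# ---------------------------------------------------------------------------
# CLI: koffkit <subcommand> --key value ...

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{featurize}, \code{pretreat},
#' \code{train}, \code{evaluate}, \code{bep}, \code{qc}, \code{pipeline}.
#' Invoked by the \code{inst/cli/koffkit} script; callable directly for
#' testing.
#'
#' @param args character vector of CLI arguments (default: the command line).
#' @return invisibly, the subcommand's result.
#' @export
koffkit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: koffkit <simulate|featurize|pretreat|train|evaluate|bep|qc|pipeline> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  opt <- parse_cli_args(args[-1L])
  seed <- as.integer(opt$seed %||% 1L)
  res <- switch(cmd,
    simulate = {
      spec <- synthetic_spec(n_ligands = as.integer(opt$`n-ligands` %||% 20L),
                             n_residues = as.integer(opt$`n-residues` %||% 5L),
                             seed = seed)
      bench <- make_synthetic_benchmark(spec)
      out_dir <- opt$`out-dir` %||% "."
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (cx in bench$complexes) {
        write_complex(cx, file.path(out_dir, paste0(cx$complex_id, ".pdb")),
                      file.path(out_dir, paste0(cx$complex_id, "_params.csv")))
      }
      write_dataset(bench$dataset, file.path(out_dir, "labels.csv"))
      write_matrix(bench$X, file.path(out_dir, "X.csv"))
      message(sprintf("wrote %d complexes + labels to %s",
                      length(bench$complexes), out_dir))
      bench
    },
    featurize = {
      cfg <- energetics_config(dielectric = as.numeric(opt$dielectric %||% 4))
      pdbs <- sort(list.files(opt$complexes, pattern = "\\.pdb$", full.names = TRUE))
      complexes <- lapply(pdbs, function(p) {
        read_complex(p, sub("\\.pdb$", "_params.csv", p),
                     ligand_name = opt$`ligand-name` %||% "LIG")
      })
      X <- build_matrix(complexes, cfg)
      write_matrix(X, opt$out %||% "X.csv")
      X
    },
    bep = {
      fit <- bep_fit(read_dataset(opt$labels))
      jsonlite::write_json(unclass(fit), opt$out %||% "bep.json",
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    qc = {
      d <- read_dataset(opt$labels)
      out <- list(label_summary = label_summary(d))
      if ("pkd" %in% names(d) && sum(is.finite(d$pkd)) >= 3) {
        out$bep <- unclass(bep_fit(d))
      }
      jsonlite::write_json(out, opt$out %||% "qc.json", auto_unbox = TRUE,
                           digits = NA)
      out
    },
    pretreat = {
      X <- read_matrix(opt$matrix)
      cfg <- pretreat_config(
        std_threshold = as.numeric(opt$`std-threshold` %||% 0),
        standardize = isTRUE(opt$standardize),
        n_components = if (!is.null(opt$`n-components`)) as.integer(opt$`n-components`))
      fp <- pretreat_fit(X, cfg)
      S <- pretreat_transform(fp, X)
      write_matrix(S, opt$out %||% "scores.csv")
      if (!is.null(opt$`save-fitted`)) save_pretreatment(fp, opt$`save-fitted`)
      fp
    },
    train = {
      S <- read_matrix(opt$scores)
      d <- read_dataset(opt$labels)
      y <- d$pkoff[match(rownames(S), d$complex_id)]
      if (anyNA(y)) stopf("labels missing for some score rows")
      model <- fit_regressor(regressor_spec(opt$model %||% "BNN", seed = seed), S, y)
      saveRDS(model, opt$out %||% "model.rds")
      model
    },
    evaluate = {
      X <- read_matrix(opt$matrix)
      d <- read_dataset(opt$labels)
      d <- d[match(rownames(X), d$complex_id), , drop = FALSE]
      class(d) <- c("kinetic_dataset", "data.frame")
      kinds <- strsplit(opt$models %||% "plsr", ",")[[1]]
      specs <- lapply(kinds, function(k) regressor_spec(k, seed = seed))
      cfg <- pretreat_config(
        n_components = if (!is.null(opt$`n-components`)) as.integer(opt$`n-components`))
      tab <- compare_models(specs, d, X, cfg)
      out <- as.data.frame(tab)
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], function(v) sprintf("%.3f", v))
      write.csv(out, opt$report %||% "report.csv", row.names = FALSE, quote = FALSE)
      tab
    },
    pipeline = run_pipeline(opt$config),
    stopf("unknown subcommand '%s'", cmd)
  )
  invisible(res)
}
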
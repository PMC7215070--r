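# End-to-end pipeline: simulate (or ingest) -> filter -> featurize -> stacked
# training -> evaluation, with per-stage caching keyed by configuration
# hashes and a JSON run manifest sufficient to re-run identically.

# md5 of an R object via its canonical JSON serialization
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.pipeline_schema <- list(
  seed = "numeric", outdir = "character", variant = "character",
  technique = "character",
  simulate = list(n_proteins = "numeric", length_range = "numeric",
                  n_motif_families = "numeric", motif_length = "numeric",
                  motif_copies = "numeric",
                  insertion_noise = "numeric", membership_probs = "numeric",
                  n_positive_pairs = "numeric", localization_count = "numeric"),
  filters = list(min_len = "numeric", max_identity = "numeric",
                 neg_ratio = "numeric", per_protein_cap = "numeric"),
  encoders = list(lag = "numeric", lambda = "numeric", omega = "numeric",
                  ld_distribution = "character", correlation = "character",
                  nonstandard = "character"),
  learners = list(techniques = "character", epochs = "numeric",
                  batch_size = "numeric", lr = "numeric",
                  val_fraction = "numeric", patience = "numeric"),
  stacking = list(K = "numeric", meta_layers = "numeric", eta = "numeric",
                  max_iters = "numeric", epsilon = "numeric"),
  evaluation = list(test_fraction = "numeric", threshold = "numeric")
)

.check_schema <- function(cfg, schema, path = "") {
  problems <- character(0)
  for (nm in names(cfg)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(schema)) {
      problems <- c(problems, paste0("unknown field: ", here))
      next
    }
    want <- schema[[nm]]
    if (is.list(want)) {
      if (!is.list(cfg[[nm]])) {
        problems <- c(problems, paste0(here, ": expected a section"))
      } else {
        problems <- c(problems, .check_schema(cfg[[nm]], want, here))
      }
    } else if (!is.null(cfg[[nm]]) &&
               !inherits(cfg[[nm]], want) && !(want == "numeric" &&
                                               is.numeric(cfg[[nm]]))) {
      if (!(want == "character" && is.character(cfg[[nm]]))) {
        problems <- c(problems, paste0(here, ": expected ", want))
      }
    }
  }
  problems
}

#' Validate and complete a pipeline configuration
#'
#' Checks a configuration (a nested list, or a path to a YAML file with the
#' same structure) against the documented schema, reporting every violation
#' with its field path before any computation, and fills unset fields with
#' the package defaults (the shipped `configs/default.yaml`).
#'
#' @param config A nested list or a YAML file path; `NULL` for the defaults.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    assert_that(file.exists(config), paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  problems <- .check_schema(config, .pipeline_schema)
  if (length(problems) > 0) {
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  defaults <- yaml::read_yaml(system.file("configs", "default.yaml",
                                          package = "stackppi"))
  merge2 <- function(d, c) {
    for (nm in names(c)) {
      d[[nm]] <- if (is.list(c[[nm]]) && is.list(d[[nm]])) {
        merge2(d[[nm]], c[[nm]])
      } else c[[nm]]
    }
    d
  }
  merge2(defaults, config)
}

.stage_paths <- function(outdir) {
  list(
    simulate = file.path(outdir, c("proteome.fasta", "localization.tsv",
                                   "positives.tsv")),
    pairs = file.path(outdir, "pairs.tsv"),
    features = NULL,  # filled per technique at run time
    split = file.path(outdir, c("train_pairs.tsv", "test_pairs.tsv")),
    folds = file.path(outdir, "fold_models.rds"),
    meta = file.path(outdir, "meta_model.rds"),
    evaluate = file.path(outdir, c("metrics.json", "predictions.tsv"))
  )
}

.load_stage_hashes <- function(outdir) {
  f <- file.path(outdir, ".stage_hashes.json")
  if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE) else list()
}

.save_stage_hashes <- function(outdir, hashes) {
  jsonlite::write_json(hashes, file.path(outdir, ".stage_hashes.json"),
                       auto_unbox = TRUE)
}

#' Run the full PPI prediction pipeline
#'
#' Executes simulate -> construct pairs -> featurize -> split -> train fold
#' models with out-of-fold meta-features -> train meta-learner -> evaluate,
#' writing every intermediate artifact under `outdir`. Each stage is keyed
#' by a hash of the configuration it depends on (chained through its
#' upstream stages), so re-running with the same configuration skips
#' completed stages and deleting a single artifact re-runs only the stages
#' that depend on it. A JSON manifest (configuration hash, seeds, file
#' digests, per-stage timings and status, package version) is written
#' atomically at the end.
#'
#' @param config Configuration list or YAML path (see [pipeline_config()]).
#' @param outdir Output directory (overrides the configured one).
#' @param verbose Print stage progress?
#' @return The run manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, verbose = TRUE) {
  cfg <- pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% "stackppi_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hashes <- .load_stage_hashes(outdir)
  paths <- .stage_paths(outdir)
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- list()
  status <- list()

  run_stage <- function(stage, subcfg, upstream, outputs, fun) {
    h <- .hash_obj(list(cfg = subcfg, upstream = upstream))
    cached <- identical(hashes[[stage]], h) && all(file.exists(outputs))
    t0 <- Sys.time()
    if (cached) {
      say("[%s] cached, skipping", stage)
      status[[stage]] <<- "skipped"
    } else {
      say("[%s] running", stage)
      fun()
      hashes[[stage]] <<- h
      .save_stage_hashes(outdir, hashes)
      status[[stage]] <<- "run"
    }
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    h
  }

  seed <- cfg$seed
  sim <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))

  h_sim <- run_stage("simulate", unclass(sim), NULL, paths$simulate, function() {
    proteome <- simulate_proteome(sim)
    net <- simulate_network(proteome, sim)
    write_fasta(proteome, paths$simulate[1])
    readr::write_tsv(proteome[, c("id", "localization")], paths$simulate[2])
    write_pairs(net$positives, paths$simulate[3])
  })

  h_pairs <- run_stage("pairs", cfg$filters, h_sim, paths$pairs, function() {
    records <- annotate_localization(read_fasta(paths$simulate[1]),
                                     read_localization(paths$simulate[2]))
    positives <- filter_positive_set(records, read_pairs(paths$simulate[3]),
                                     min_len = cfg$filters$min_len,
                                     max_identity = cfg$filters$max_identity)
    negatives <- sample_negatives(records, positives,
                                  ratio = cfg$filters$neg_ratio,
                                  per_protein_cap = cfg$filters$per_protein_cap,
                                  seed = derive_seed(seed, "negatives"))
    write_pairs(bind_pair_sets(positives, negatives), paths$pairs)
  })

  techs <- cfg$learners$techniques
  feat_paths <- file.path(outdir, sprintf("features_%s.tsv", techs))
  h_feat <- run_stage("features", cfg$encoders, h_pairs, feat_paths, function() {
    records <- read_fasta(paths$simulate[1])
    for (i in seq_along(techs)) {
      ft <- encode_proteins(records, techs[i],
                            lag = cfg$encoders$lag,
                            lambda = cfg$encoders$lambda,
                            omega = cfg$encoders$omega,
                            ld_distribution = cfg$encoders$ld_distribution,
                            correlation = cfg$encoders$correlation,
                            nonstandard = cfg$encoders$nonstandard)
      readr::write_tsv(ft, feat_paths[i])
    }
  })

  h_split <- run_stage("split", cfg$evaluation["test_fraction"], h_pairs,
                       paths$split, function() {
    pairs <- read_pairs(paths$pairs)
    test_id <- with_local_seed(derive_seed(seed, "split"), {
      unlist(lapply(c(0L, 1L), function(cl) {
        ids <- which(pairs$label == cl)
        sample(ids, round(cfg$evaluation$test_fraction * length(ids)))
      }))
    })
    write_pairs(pairs[-test_id, ], paths$split[1])
    write_pairs(pairs[test_id, ], paths$split[2])
  })

  stack_cfg <- stacking_config(
    K = cfg$stacking$K,
    learners = default_learner_grid(
      techniques = techs, epochs = cfg$learners$epochs,
      batch_size = cfg$learners$batch_size, lr = cfg$learners$lr,
      val_fraction = cfg$learners$val_fraction,
      patience = cfg$learners$patience, seed = derive_seed(seed, "learners")
    ),
    meta_layers = cfg$stacking$meta_layers, eta = cfg$stacking$eta,
    max_iters = cfg$stacking$max_iters, epsilon = cfg$stacking$epsilon,
    seed = derive_seed(seed, "stacking")
  )
  variant <- cfg$variant %||% "grid"
  if (variant != "grid") {
    proto <- stack_cfg$learners[[1]]
    stack_cfg$learners <- default_learner_grid(
      techniques = if (variant == "concat") "concat" else cfg$technique,
      epochs = proto$epochs, batch_size = proto$batch_size, lr = proto$lr,
      val_fraction = proto$val_fraction, patience = proto$patience,
      seed = stack_cfg$seed
    )
  }

  read_features <- function() {
    fl <- lapply(feat_paths, function(p) {
      readr::read_tsv(p, col_types = readr::cols(
        id = readr::col_character(), .default = readr::col_double()
      ))
    })
    names(fl) <- techs
    fl
  }

  h_folds <- run_stage("folds",
                       list(stack = cfg$stacking, learners = cfg$learners,
                            variant = variant, technique = cfg$technique),
                       c(h_feat, h_split), paths$folds, function() {
    train_pairs <- read_pairs(paths$split[1])
    mf <- build_meta_features(train_pairs, read_features(), stack_cfg,
                              verbose = verbose)
    saveRDS(list(mf = mf, labels = train_pairs$label), paths$folds)
  })

  h_meta <- run_stage("meta", cfg$stacking["meta_layers"], h_folds,
                      paths$meta, function() {
    fold_blob <- readRDS(paths$folds)
    meta_model <- train_meta(fold_blob$mf$meta, fold_blob$labels, stack_cfg)
    saveRDS(meta_model, paths$meta)
  })

  run_stage("evaluate", cfg$evaluation, h_meta, paths$evaluate, function() {
    fold_blob <- readRDS(paths$folds)
    meta_model <- readRDS(paths$meta)
    test_pairs <- read_pairs(paths$split[2])
    tm <- predict_meta_features(test_pairs, read_features(),
                                fold_blob$mf$fold_models, stack_cfg$learners)
    preds <- tibble::tibble(idA = test_pairs$idA, idB = test_pairs$idB,
                            label = test_pairs$label,
                            .pred = predict(meta_model, tm))
    readr::write_tsv(preds, paths$evaluate[2])
    ev <- evaluate_predictions(preds, threshold = cfg$evaluation$threshold)
    jsonlite::write_json(as.list(ev[1, ]), paths$evaluate[1],
                         auto_unbox = TRUE, digits = NA)
  })

  all_out <- c(paths$simulate, paths$pairs, feat_paths, paths$split,
               paths$folds, paths$meta, paths$evaluate)
  manifest <- list(
    package_version = as.character(utils::packageVersion("stackppi")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    config_hash = .hash_obj(cfg),
    seed = seed,
    stage_status = status,
    stage_seconds = timings,
    outputs = as.list(tools::md5sum(all_out[file.exists(all_out)]))
  )
  tmp <- tempfile(tmpdir = outdir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(outdir, "manifest.json"))
  class(manifest) <- "ppi_manifest"
  invisible(manifest)
}
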
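#' Read and validate an experiment configuration
#'
#' Experiment configs are JSON objects with blocks `dataset`, `model`,
#' `train`, `prune`, plus `out_dir` and a master `seed` that fans out to
#' named sub-streams for data generation, initialisation, sampling and
#' evaluation. Unknown fields are rejected so typos fail loudly.
#'
#' @param path path to a JSON config file.
#' @return validated config list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param cfg a config list (as from JSON).
#' @export
as_experiment_config <- function(cfg) {
  allowed <- c("dataset", "model", "train", "prune", "out_dir", "seed")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    stop(sprintf("unknown config fields: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$dataset) || is.null(cfg$model)) {
    stop("config must contain 'dataset' and 'model' blocks", call. = FALSE)
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "prunebm-run"
  structure(cfg, class = "experiment_config")
}

build_dataset <- function(ds, seed) {
  kind <- ds$kind %||% "mixture"
  switch(kind,
    mixture = {
      protos <- if (!is.null(ds$prototypes)) as.matrix(ds$prototypes)
                else default_patch_prototypes()
      generate_mixture(protos, ds$n_samples %||% 2000,
                       class_weights = ds$class_weights,
                       flip_prob = ds$flip_prob %||% 0.05,
                       seed = sub_seed(seed, "data"))
    },
    toy_digits = toy_digits(ds$n_samples %||% 1000,
                            n_classes = ds$n_classes %||% 10,
                            flip_prob = ds$flip_prob %||% 0.05,
                            seed = sub_seed(seed, "data")),
    file = read_binary_dataset(ds$path),
    stop(sprintf("unknown dataset kind '%s'", kind), call. = FALSE)
  )
}

build_train_config <- function(tr, seed) {
  tr <- tr %||% list()
  tr$seed <- tr$seed %||% sub_seed(seed, "train")
  do.call(train_config, tr)
}

build_prune_config <- function(pr, seed) {
  pr <- pr %||% list()
  pr$seed <- pr$seed %||% sub_seed(seed, "prune")
  do.call(prune_config, pr)
}

#' Run a full generate/train/prune/evaluate experiment
#'
#' Executes the pipeline described by a config: build or load the dataset,
#' train the model (RBM, or pretrained+jointly-trained deep network when the
#' model block lists two hidden layers), run the iterative prune-retrain
#' loop, and write artifacts (dataset archive, model checkpoints, the
#' pruning report as CSV and JSON) into `out_dir`. Runs are reproducible
#' byte-for-byte given the same config and seed.
#'
#' @param config an `experiment_config`, a config list, or a path to a JSON
#'   config file.
#' @return the [prune_loop()] report, invisibly; artifacts on disk.
#' @export
run_experiment <- function(config) {
  cfg <- if (is.character(config)) read_experiment_config(config)
         else as_experiment_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  data <- build_dataset(cfg$dataset, seed)
  write_binary_dataset(data, file.path(cfg$out_dir, "dataset.json"))
  train_cfg <- build_train_config(cfg$train, seed)
  n_hidden <- cfg$model$n_hidden
  mask1 <- if (!is.null(cfg$model$receptive_field)) {
    rf <- cfg$model$receptive_field
    receptive_field_mask(data$layout[1], data$layout[2],
                         field = rf$field %||% 5, stride = rf$stride %||% 1)
  } else NULL
  net <- if (length(n_hidden) == 1) {
    train_rbm(data, n_hidden, train_cfg, mask = mask1)
  } else {
    stack <- pretrain_stack(data, n_hidden, train_cfg, train_cfg, mask1 = mask1)
    pcd_train(stack, data, train_cfg)
  }
  write_checkpoint(net, file.path(cfg$out_dir, "model_initial.json"),
                   history = list(seed = seed, stage = "trained"))
  report <- NULL
  if (!is.null(cfg$prune)) {
    prune_cfg <- build_prune_config(cfg$prune, seed)
    report <- prune_loop(net, data, prune_cfg, train_cfg)
    if (!is.null(report$final_net)) {
      write_checkpoint(report$final_net,
                       file.path(cfg$out_dir, "model_pruned.json"),
                       history = list(seed = seed, stage = "pruned",
                                      criterion = prune_cfg$criterion))
    }
    if (!is.null(report$records)) {
      utils::write.csv(report$records,
                       file.path(cfg$out_dir, "prune_report.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(criterion = report$criterion, seed = report$seed,
           stopped_early = report$stopped_early, records = report$records),
      file.path(cfg$out_dir, "prune_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}

#' Aggregate pruning reports across seeds
#'
#' Summarises a list of [prune_loop()] reports run under the same
#' configuration but different seeds: per criterion and iteration, the mean
#' and standard deviation of remaining weights, remaining units and the
#' evaluation metrics.
#'
#' @param reports list of `prune_run_report`s.
#' @return data.frame with one row per (criterion, iteration) and
#'   `mean`/`sd` columns per tracked quantity.
#' @export
summarize <- function(reports) {
  stopifnot(length(reports) >= 1)
  recs <- lapply(reports, function(r) {
    if (is.null(r$records)) return(NULL)
    cbind(criterion = r$criterion, seed = r$seed, r$records)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) stop("no completed iterations to summarise", call. = FALSE)
  iters <- sort(unique(recs$iteration))
  crits <- unique(recs$criterion)
  num_cols <- setdiff(names(recs)[vapply(recs, is.numeric, logical(1))],
                      c("seed", "iteration"))
  # all reports must track the same quantities
  rows <- list()
  for (cr in crits) {
    for (it in iters) {
      sub <- recs[recs$criterion == cr & recs$iteration == it, , drop = FALSE]
      if (nrow(sub) == 0) next
      row <- data.frame(criterion = cr, iteration = it, n_seeds = nrow(sub))
      for (cl in num_cols) {
        s <- stats::sd(sub[[cl]])
        row[[paste0(cl, "_mean")]] <- mean(sub[[cl]])
        row[[paste0(cl, "_sd")]] <- if (is.na(s)) 0 else s
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
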
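# Hierarchical step -> trace -> person model for functional-stage
# prediction: per-level networks pretrained against stage labels ("teacher
# enforcing"), class-probability outputs passed upward through mean
# aggregation, then joint end-to-end fine-tuning.

step_feature_names <- c("step_time", "toe_prob", "sensor", "mean", "sd",
                        "skewness", "kurtosis", "dom_freq_strike",
                        "dom_freq_off", "psd1", "psd2", "psd3")
trace_feature_names <- c("symmetry", "step_time_var", "cadence",
                         "energy_var", paste0("rpsd", 1:10))
stage_levels <- 0:5

#' Assemble a step-level feature matrix
#'
#' Fixed, documented column order for the step level: step time, toe-contact
#' probability, sensor number, the four basic signal statistics, the two
#' dominant frequencies, and three PSD band powers (12 dimensions by
#' default). Non-finite entries are rejected.
#'
#' @param step_df data.frame containing at least the step feature columns.
#' @return Numeric matrix with columns in canonical order.
#' @export
assemble_step_features <- function(step_df) {
  missing <- setdiff(step_feature_names, names(step_df))
  if (length(missing) > 0) {
    stop("missing step features: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(step_df[, step_feature_names, drop = FALSE])
  if (any(!is.finite(m))) stop("non-finite step feature values")
  m
}

#' Element-wise mean aggregation of embeddings
#'
#' Mean over the members of a group (steps of a trace, traces of a person);
#' dimension-preserving and permutation-invariant.
#'
#' @param embeddings Numeric matrix (one member per row) or vector (single
#'   member).
#' @return Numeric vector: the element-wise mean.
#' @export
aggregate_mean <- function(embeddings) {
  if (is.null(dim(embeddings))) return(as.numeric(embeddings))
  if (nrow(embeddings) == 0) stop("empty group")
  colMeans(embeddings)
}

#' Build the trace-level input vector
#'
#' Mean of the step-level class-probability vectors of the trace's steps,
#' concatenated with the (standardized) trace features: 6 + 14 = 20
#' dimensions by default.
#'
#' @param step_probs Matrix of per-step class probabilities (rows sum to 1).
#' @param trace_features Numeric vector of trace-level features.
#' @return Numeric vector of length `ncol(step_probs) + length(trace_features)`.
#' @export
build_trace_input <- function(step_probs, trace_features) {
  if (is.null(dim(step_probs))) step_probs <- matrix(step_probs, nrow = 1)
  if (nrow(step_probs) == 0) stop("trace without steps")
  c(aggregate_mean(step_probs), as.numeric(trace_features))
}

# Per-feature standardization fitted on training rows only.
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_standardizer <- function(std, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
}

default_hier_config <- function() {
  list(step_hidden = c(256, 64), trace_hidden = c(128, 32),
       person_hidden = 64,
       dropout = 0.2, lr = 1e-3, epochs = 150, patience = 25,
       finetune_epochs = 40, finetune_lr = 3e-4,
       test_fraction = 0.2, split = "footstep")
}

#' Pretrain one hierarchy level
#'
#' Trains the level's multi-layer network (rectifier activations, 20%
#' dropout, softmax cross-entropy head) against functional-stage labels
#' broadcast to that level's samples — the "teacher enforcing" step that
#' lets each level learn stage-related structure before aggregation.
#'
#' @param level `"step"`, `"trace"` or `"person"` (selects the configured
#'   widths: 12-256-64, 20-128-32, 9-64, each with a 6-way head).
#' @param features Numeric matrix of standardized inputs for this level.
#' @param stages Integer vector of stage labels 0-5, one per row.
#' @param config List of training hyperparameters (see
#'   [train_hierarchical()]).
#' @param seed Integer seed.
#' @return An internal network object with a class-probability head.
#' @export
pretrain_level <- function(level = c("step", "trace", "person"), features,
                           stages, config = list(), seed = 1) {
  level <- match.arg(level)
  cfg <- utils::modifyList(default_hier_config(), config)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(stages), all(stages %in% stage_levels))
  if (length(unique(stages)) < 2) {
    stop("pretraining requires at least 2 distinct stages")
  }
  hidden <- switch(level, step = cfg$step_hidden, trace = cfg$trace_hidden,
                   person = cfg$person_hidden)
  net <- mlp_init(ncol(features), hidden, length(stage_levels), seed = seed)
  mlp_train(net, features, as.integer(stages) + 1L, epochs = cfg$epochs,
            lr = cfg$lr, dropout = cfg$dropout, patience = cfg$patience,
            seed = seed + 1L)
}

#' Class probabilities from a level network
#'
#' Inference-mode forward pass (dropout disabled, hence deterministic).
#'
#' @param net A pretrained level network.
#' @param X Input matrix or vector.
#' @return Matrix of stage probabilities, rows summing to 1.
#' @export
level_probs <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  mlp_forward(net, X)$probs
}

# ---- cohort feature container ------------------------------------------

# `cohort_features` is a list of persons:
#   person$stage       integer 0-5
#   person$biometrics  fg_biometrics
#   person$traces      list of trace: $features (named, trace_feature_names)
#                                     $steps (matrix, step_feature_names)
validate_cohort_features <- function(cohort_features) {
  stopifnot(length(cohort_features) >= 2)
  for (p in cohort_features) {
    stopifnot(!is.null(p$stage), p$stage %in% stage_levels,
              inherits(p$biometrics, "fg_biometrics"),
              length(p$traces) >= 1)
    for (tr in p$traces) {
      stopifnot(identical(colnames(tr$steps), step_feature_names),
                identical(names(tr$features), trace_feature_names))
    }
  }
  invisible(TRUE)
}

biometric_vector <- function(bio) {
  c(age = bio$age, gender = as.numeric(bio$gender == "male"), bmi = bio$bmi)
}

# Flatten the cohort into indexed matrices: steps with trace ids, traces
# with person ids.
flatten_cohort <- function(cohort_features) {
  steps <- list(); step_trace <- integer(0)
  tfeat <- list(); trace_person <- integer(0)
  y_person <- integer(0)
  bio <- list()
  tid <- 0L
  for (k in seq_along(cohort_features)) {
    p <- cohort_features[[k]]
    y_person[k] <- p$stage
    bio[[k]] <- biometric_vector(p$biometrics)
    for (tr in p$traces) {
      tid <- tid + 1L
      steps[[tid]] <- tr$steps
      step_trace <- c(step_trace, rep(tid, nrow(tr$steps)))
      tfeat[[tid]] <- tr$features
      trace_person <- c(trace_person, k)
    }
  }
  list(X_step = do.call(rbind, steps), step_trace = step_trace,
       trace_features = do.call(rbind, tfeat), trace_person = trace_person,
       y_person = y_person, biometrics = do.call(rbind, bio))
}

group_means <- function(M, group, n_groups) {
  out <- matrix(0, n_groups, ncol(M))
  cnt <- tabulate(group, n_groups)
  for (j in seq_len(ncol(M))) {
    out[, j] <- tapply(M[, j], factor(group, levels = seq_len(n_groups)),
                       mean)
  }
  list(means = out, counts = cnt)
}

#' Train the hierarchical stage predictor
#'
#' Three-phase training mirroring the model's design: (1) the step, trace
#' and person networks are pretrained in order against stage labels
#' broadcast to their level ("teacher enforcing"), with each level's 6-way
#' class-probability output aggregated by the element-wise mean and passed
#' upward as part of the next level's input; (2) the whole hierarchy is
#' fine-tuned end to end, with gradients flowing from the person-level loss
#' through the mean aggregations back to the step network (the three
#' levels' cross-entropy losses are averaged so the teacher signal is
#' retained during joint training); (3) standardization statistics, fitted
#' on training footsteps only, are stored with the model.
#'
#' The train/test split is at footstep granularity by default (80/20 within
#' each trace); `config$split = "subject"` holds out whole subjects
#' instead.
#'
#' @param cohort_features List of person feature bundles; see
#'   [extract_cohort_features()].
#' @param config Optional overrides of the training configuration
#'   (`step_hidden`, `trace_hidden`, `person_hidden`, `dropout`, `lr`,
#'   `epochs`, `finetune_epochs`, `finetune_lr`, `test_fraction`, `split`).
#' @param seed Integer seed; fixed seeds give identical models.
#' @return Object of class `fg_hier_model` with the three networks,
#'   standardizers, configuration, and the train/test split bookkeeping.
#' @export
train_hierarchical <- function(cohort_features, config = list(), seed = 1) {
  cfg <- utils::modifyList(default_hier_config(), config)
  validate_cohort_features(cohort_features)
  flat <- flatten_cohort(cohort_features)
  if (length(unique(flat$y_person)) < 2) {
    stop("training requires at least 2 distinct stages in the cohort")
  }
  n_steps <- nrow(flat$X_step)
  n_traces <- nrow(flat$trace_features)
  n_persons <- length(flat$y_person)
  y_step <- flat$y_person[flat$trace_person[flat$step_trace]]
  y_trace <- flat$y_person[flat$trace_person]

  withr::with_seed(as.integer(seed), {
    if (identical(cfg$split, "subject")) {
      test_persons <- sample.int(n_persons,
                                 max(1L, round(cfg$test_fraction * n_persons)))
      test_step <- flat$trace_person[flat$step_trace] %in% test_persons
    } else {
      # footstep-level split, stratified within each trace so every trace
      # keeps at least one training step
      test_step <- logical(n_steps)
      for (j in seq_len(n_traces)) {
        idx <- which(flat$step_trace == j)
        n_te <- min(length(idx) - 1L,
                    base::floor(cfg$test_fraction * length(idx)))
        if (n_te > 0) test_step[sample(idx, n_te)] <- TRUE
      }
    }

    train_idx <- which(!test_step)
    step_std <- fit_standardizer(flat$X_step[train_idx, , drop = FALSE])
    Xs <- apply_standardizer(step_std, flat$X_step)

    # -- step level pretraining (training footsteps only)
    step_net <- pretrain_level("step", Xs[train_idx, , drop = FALSE],
                               y_step[train_idx], cfg, seed = seed + 11L)

    trace_std <- fit_standardizer(flat$trace_features)
    Tf <- apply_standardizer(trace_std, flat$trace_features)

    trace_input <- function(net, use_steps) {
      P <- level_probs(net, Xs)
      t(vapply(seq_len(n_traces), function(j) {
        idx <- which(flat$step_trace == j & use_steps)
        if (length(idx) == 0) idx <- which(flat$step_trace == j)
        build_trace_input(P[idx, , drop = FALSE], Tf[j, ])
      }, numeric(length(stage_levels) + ncol(Tf))))
    }
    Ti_train <- trace_input(step_net, !test_step)

    trace_net <- pretrain_level("trace", Ti_train, y_trace, cfg,
                                seed = seed + 23L)

    bio_std <- fit_standardizer(flat$biometrics)
    Bf <- apply_standardizer(bio_std, flat$biometrics)

    person_input <- function(Pt) {
      t(vapply(seq_len(n_persons), function(k) {
        idx <- which(flat$trace_person == k)
        c(aggregate_mean(Pt[idx, , drop = FALSE]), Bf[k, ])
      }, numeric(length(stage_levels) + ncol(Bf))))
    }
    Pi_train <- person_input(level_probs(trace_net, Ti_train))

    person_net <- pretrain_level("person", Pi_train, flat$y_person, cfg,
                                 seed = seed + 37L)

    # -- joint fine-tuning: averaged step/trace/person cross-entropies,
    #    full backprop through both mean aggregations
    nets <- finetune_hierarchy(
      step_net, trace_net, person_net, Xs, Tf, Bf, flat,
      train_idx = train_idx, y_step = y_step, y_trace = y_trace,
      cfg = cfg)

    structure(
      list(step_net = nets$step, trace_net = nets$trace,
           person_net = nets$person,
           step_std = step_std, trace_std = trace_std, bio_std = bio_std,
           config = cfg, classes = stage_levels,
           test_step = test_step,
           step_feature_names = step_feature_names,
           trace_feature_names = trace_feature_names),
      class = "fg_hier_model")
  })
}

finetune_hierarchy <- function(step_net, trace_net, person_net, Xs, Tf, Bf,
                               flat, train_idx, y_step, y_trace, cfg) {
  n_traces <- nrow(Tf)
  n_persons <- length(flat$y_person)
  K <- length(stage_levels)
  st_tr <- flat$step_trace[train_idx]
  Xs_tr <- Xs[train_idx, , drop = FALSE]
  ys_tr <- y_step[train_idx] + 1L
  Ys <- matrix(0, length(ys_tr), K); Ys[cbind(seq_along(ys_tr), ys_tr)] <- 1
  Yt <- matrix(0, n_traces, K); Yt[cbind(seq_len(n_traces), y_trace + 1L)] <- 1
  Yp <- matrix(0, n_persons, K)
  Yp[cbind(seq_len(n_persons), flat$y_person + 1L)] <- 1

  states <- list(step = adam_init(step_net), trace = adam_init(trace_net),
                 person = adam_init(person_net))
  w <- 1 / 3    # equal weighting of the three level losses
  for (e in seq_len(cfg$finetune_epochs)) {
    fwd_s <- mlp_forward(step_net, Xs_tr, dropout = cfg$dropout,
                         training = TRUE)
    gm <- group_means(fwd_s$probs, st_tr, n_traces)
    Ti <- cbind(gm$means, Tf)
    fwd_t <- mlp_forward(trace_net, Ti, dropout = cfg$dropout,
                         training = TRUE)
    gp <- group_means(fwd_t$probs, flat$trace_person, n_traces * 0 +
                        n_persons)
    Pi <- cbind(gp$means, Bf)
    fwd_p <- mlp_forward(person_net, Pi, dropout = cfg$dropout,
                         training = TRUE)

    bwd_p <- mlp_backward(person_net, fwd_p,
                          grad_logits = w * (fwd_p$probs - Yp) / n_persons)
    # distribute the person-input probability gradient to each trace
    grad_pt <- bwd_p$dX[flat$trace_person, seq_len(K), drop = FALSE] /
      pmax(gp$counts[flat$trace_person], 1)
    bwd_t <- mlp_backward(trace_net, fwd_t,
                          grad_logits = w * (fwd_t$probs - Yt) / n_traces,
                          grad_probs = grad_pt)
    grad_ts <- bwd_t$dX[st_tr, seq_len(K), drop = FALSE] /
      pmax(gm$counts[st_tr], 1)
    bwd_s <- mlp_backward(step_net, fwd_s,
                          grad_logits = w * (fwd_s$probs - Ys) /
                            length(ys_tr),
                          grad_probs = grad_ts)

    up <- adam_step(person_net, bwd_p$grads, states$person, t = e,
                    lr = cfg$finetune_lr)
    person_net <- up$net; states$person <- up$state
    up <- adam_step(trace_net, bwd_t$grads, states$trace, t = e,
                    lr = cfg$finetune_lr)
    trace_net <- up$net; states$trace <- up$state
    up <- adam_step(step_net, bwd_s$grads, states$step, t = e,
                    lr = cfg$finetune_lr)
    step_net <- up$net; states$step <- up$state
  }
  list(step = step_net, trace = trace_net, person = person_net)
}

# Forward pass over a person bundle (list with $traces, $biometrics) using
# the trained model; inference mode throughout.
hier_forward_person <- function(model, person) {
  probs_traces <- lapply(person$traces, function(tr) {
    Xs <- apply_standardizer(model$step_std, tr$steps)
    Ps <- level_probs(model$step_net, Xs)
    Tf <- apply_standardizer(model$trace_std,
                             tr$features[model$trace_feature_names])
    ti <- build_trace_input(Ps, as.numeric(Tf))
    level_probs(model$trace_net, ti)
  })
  Pt <- do.call(rbind, probs_traces)
  Bf <- apply_standardizer(model$bio_std,
                           biometric_vector(person$biometrics))
  pi <- c(aggregate_mean(Pt), as.numeric(Bf))
  as.numeric(level_probs(model$person_net, pi))
}

#' Predict the functional stage of a person
#'
#' Runs the person's traces through the trained hierarchy (inference mode,
#' dropout disabled, hence deterministic) and returns the stage probability
#' vector and its argmax; ties break toward the lower (less severe
#' estimate, clinically conservative) stage.
#'
#' @param model An [train_hierarchical()] result.
#' @param person List with `traces` (each with `steps` matrix and
#'   `features` vector) and `biometrics`.
#' @return List with `probabilities` (named p0..p5, summing to 1) and
#'   `stage`.
#' @export
predict_stage <- function(model, person) {
  stopifnot(inherits(model, "fg_hier_model"))
  if (length(person$traces) < 1) stop("prediction requires at least 1 trace")
  pr <- hier_forward_person(model, person)
  names(pr) <- paste0("p", stage_levels)
  list(probabilities = pr, stage = stage_levels[which.max(pr)])
}

#' Per-level accuracies on the held-out footsteps
#'
#' Evaluates the trained hierarchy at all three levels using the test-split
#' footsteps: step-level accuracy over test steps, trace-level accuracy
#' with trace inputs aggregated from test steps, and person-level accuracy
#' with the full upward pass.
#'
#' @param model An [train_hierarchical()] result.
#' @param cohort_features The cohort the model was trained on.
#' @return List with `step`, `trace`, `person` accuracies and the
#'   person-level predictions.
#' @export
evaluate_hierarchical <- function(model, cohort_features) {
  stopifnot(inherits(model, "fg_hier_model"))
  flat <- flatten_cohort(cohort_features)
  K <- length(stage_levels)
  test <- model$test_step
  if (!any(test)) test <- !test   # degenerate: no held-out steps
  Xs <- apply_standardizer(model$step_std, flat$X_step)
  Ps <- level_probs(model$step_net, Xs)
  y_step <- flat$y_person[flat$trace_person[flat$step_trace]]
  acc_step <- mean((max.col(Ps[test, , drop = FALSE], "first") - 1) ==
                     y_step[test])

  Tf <- apply_standardizer(model$trace_std, flat$trace_features)
  n_traces <- nrow(Tf)
  Ti <- t(vapply(seq_len(n_traces), function(j) {
    idx <- which(flat$step_trace == j & test)
    if (length(idx) == 0) idx <- which(flat$step_trace == j)
    build_trace_input(Ps[idx, , drop = FALSE], Tf[j, ])
  }, numeric(K + ncol(Tf))))
  Pt <- level_probs(model$trace_net, Ti)
  y_trace <- flat$y_person[flat$trace_person]
  acc_trace <- mean((max.col(Pt, "first") - 1) == y_trace)

  Bf <- apply_standardizer(model$bio_std, flat$biometrics)
  n_persons <- length(flat$y_person)
  Pi <- t(vapply(seq_len(n_persons), function(k) {
    idx <- which(flat$trace_person == k)
    c(aggregate_mean(Pt[idx, , drop = FALSE]), Bf[k, ])
  }, numeric(K + ncol(Bf))))
  Pp <- level_probs(model$person_net, Pi)
  pred_person <- max.col(Pp, "first") - 1
  acc_person <- mean(pred_person == flat$y_person)

  list(step = acc_step, trace = acc_trace, person = acc_person,
       person_predictions = pred_person, person_truth = flat$y_person,
       n_test_steps = sum(test), n_traces = n_traces,
       n_persons = n_persons)
}
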
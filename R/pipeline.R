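# End-to-end experiment orchestration on synthetic phantoms: generate cases,
# extract surfaces, project ground truth, train the potential networks,
# classify scars with graph-cuts, run the classical baselines, and evaluate
# everything on surface nodes. Fully deterministic given the global seed.

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run. Defaults are the reference
#' values (three scales, 13 x 13 x 17 patches, R = 8 mm, lambda = 0.4, the
#' standard SGD protocol); tests and examples override toward smaller,
#' CPU-sized problems.
#'
#' @param n_train,n_test Number of training / test phantoms.
#' @param phantom Named list of [phantom_config()] arguments (per-case seeds
#'   are supplied by the pipeline).
#' @param msp An [msp_config()]; its `shift_R_mm` is the training-time R.
#' @param arch A [net_config()].
#' @param train_t,train_n [train_config()]s for the two networks (seeds are
#'   derived from the global seed).
#' @param lambda Graph-cuts balancing parameter.
#' @param use_auto_seg If `TRUE` (fully automatic setting) surfaces are
#'   extracted from the perturbed automatic LA segmentation and the method
#'   is scored against ground truth projected on that surface; baselines
#'   always use the manual LA segmentation and its surface.
#' @param baselines Run the four classical baselines on the test cases.
#' @param wall_dilation_mm Wall-mask dilation for the baselines.
#' @param depth_out_mm,depth_in_mm Label projection corridor.
#' @param max_train_nodes,max_train_edges Optional caps on the balanced
#'   node/edge training samples per case (uniform subsample); keeps small
#'   reference runs fast without changing the sampling rule.
#' @param mgmm_K_scar,mgmm_K_normal MGMM components per class.
#' @param smooth_iter Mesh smoothing iterations in surface extraction.
#' @param out_dir Optional output directory for CSV reports.
#' @param seed Global seed; every stochastic stage derives its own stream.
#' @param verbose Print stage progress.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 2L, n_test = 1L,
                              phantom = list(),
                              msp = msp_config(),
                              arch = net_config(),
                              train_t = train_config(epochs = 15L),
                              train_n = train_config(epochs = 10L),
                              lambda = 0.4,
                              use_auto_seg = TRUE,
                              baselines = TRUE,
                              wall_dilation_mm = 3,
                              depth_out_mm = 4, depth_in_mm = 1,
                              max_train_nodes = Inf,
                              max_train_edges = Inf,
                              mgmm_K_scar = 2L, mgmm_K_normal = 3L,
                              smooth_iter = 10L,
                              out_dir = NULL,
                              seed = 1L,
                              verbose = FALSE) {
  stopifnot(n_train >= 1, n_test >= 1, lambda >= 0)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 phantom = phantom, msp = msp, arch = arch,
                 train_t = train_t, train_n = train_n, lambda = lambda,
                 use_auto_seg = use_auto_seg, baselines = baselines,
                 wall_dilation_mm = wall_dilation_mm,
                 depth_out_mm = depth_out_mm, depth_in_mm = depth_in_mm,
                 max_train_nodes = max_train_nodes,
                 max_train_edges = max_train_edges,
                 mgmm_K_scar = as.integer(mgmm_K_scar),
                 mgmm_K_normal = as.integer(mgmm_K_normal),
                 smooth_iter = smooth_iter,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "experiment_config")
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

# Build one case bundle: phantom, working mesh, projected ground truth.
prepare_case <- function(cfg, case_idx) {
  pargs <- cfg$phantom
  pargs$seed <- derive_seed(cfg$seed, case_idx)
  truth <- make_phantom(do.call(phantom_config, pargs))
  seg <- if (cfg$use_auto_seg) truth$la_seg_auto else truth$la_seg
  mesh <- extract_surface(seg, truth$spacing, truth$origin,
                          smooth_iter = cfg$smooth_iter)
  labels <- project_labels(
    image_volume(truth$scar_seg * 1, truth$spacing, truth$origin), mesh,
    depth_out_mm = cfg$depth_out_mm, depth_in_mm = cfg$depth_in_mm)
  list(truth = truth, image_norm = normalize_volume(truth$image),
       mesh = mesh, labels = labels,
       dice_la = dice_voxel(truth$la_seg, truth$la_seg_auto))
}

# Balanced edge sample for pairwise training: all edges touching a scar or
# scar-boundary node plus an equal-sized random sample of the remaining
# (background) edges.
sample_edges <- function(mesh, labels, seed = NULL, max_edges = Inf) {
  ed <- mesh$edges
  ts <- make_training_set(mesh, labels, seed = derive_seed(seed %||% 0, 1))
  roi <- c(ts$scar, ts$boundary)
  on_roi <- (ed[, 1] %in% roi) | (ed[, 2] %in% roi)
  pos <- which(on_roi)
  bg_pool <- which(!on_roi)
  bg <- with_seed(derive_seed(seed %||% 0, 2),
                  sample(bg_pool, min(length(pos), length(bg_pool))))
  out <- c(pos, bg)
  if (length(out) > max_edges)
    out <- with_seed(derive_seed(seed %||% 0, 3), sample(out, max_edges))
  sort(out)
}

# Per-epoch training-data providers (gamma redrawn each call from the
# current RNG stream, i.e. once per node per epoch).
t_provider <- function(cases, cfg) {
  force(cases)
  function(epoch) {
    Xs <- NULL
    y <- c()
    for (cs in cases) {
      b <- extract_msp_batch(cs$image_norm, cs$mesh, cs$train_nodes$nodes,
                             cfg$msp)
      Xs <- if (is.null(Xs)) b$X else
        lapply(seq_along(Xs), function(s) rbind(Xs[[s]], b$X[[s]]))
      y <- c(y, cs$train_nodes$labels)
    }
    list(X = Xs, y = y)
  }
}

n_provider <- function(cases, cfg) {
  force(cases)
  function(epoch) {
    Xi <- Xj <- NULL
    dd <- c(); y <- c()
    for (cs in cases) {
      ed <- cs$mesh$edges[cs$train_edges, , drop = FALSE]
      un <- sort(unique(as.vector(ed)))
      b <- extract_msp_batch(cs$image_norm, cs$mesh, un, cfg$msp)
      ri <- match(ed[, 1], un)
      rj <- match(ed[, 2], un)
      bi <- lapply(b$X, function(m) m[ri, , drop = FALSE])
      bj <- lapply(b$X, function(m) m[rj, , drop = FALSE])
      Xi <- if (is.null(Xi)) bi else
        lapply(seq_along(Xi), function(s) rbind(Xi[[s]], bi[[s]]))
      Xj <- if (is.null(Xj)) bj else
        lapply(seq_along(Xj), function(s) rbind(Xj[[s]], bj[[s]]))
      dd <- c(dd, edge_lengths(cs$mesh)[cs$train_edges])
      y <- c(y, label_similarity(cs$labels[ed[, 1]], cs$labels[ed[, 2]]))
    }
    list(Xi = Xi, Xj = Xj, d = dd, y = y)
  }
}

metrics_row <- function(case, method, rep, dice_la) {
  data.frame(case = case, method = method, n_nodes = rep$n_nodes,
             accuracy = rep$accuracy, sensitivity = rep$sensitivity,
             specificity = rep$specificity, dice_scar = rep$dice_scar,
             gdice = rep$gdice, dice_la = dice_la,
             stringsAsFactors = FALSE)
}

#' Run the full phantom experiment pipeline
#'
#' Generates training and test phantoms, extracts surfaces (from the
#' automatic LA segmentation in the fully automatic setting), projects the
#' scar ground truth, trains the unary and pairwise networks with balanced
#' sampling and random patch shifts, classifies the test surfaces by
#' graph-cuts, optionally runs the classical baselines on the manual-LA
#' wall, and reports surface-node metrics.
#'
#' @param cfg An [experiment_config()].
#' @return List of class `pipeline_result`: `per_case` (one metrics row per
#'   case and method), `summary` (mean/SD by method), `theta_t`, `theta_n`,
#'   `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  n_cases <- cfg$n_train + cfg$n_test
  say(cfg, "generating ", n_cases, " phantoms")
  cases <- lapply(seq_len(n_cases), function(i) {
    cs <- prepare_case(cfg, i)
    say(cfg, "  case ", i, ": ", nrow(cs$mesh$vertices), " nodes, ",
        sum(cs$labels), " scar nodes, LA Dice ", round(cs$dice_la, 3))
    cs
  })
  train_cases <- cases[seq_len(cfg$n_train)]
  test_cases <- cases[cfg$n_train + seq_len(cfg$n_test)]

  for (i in seq_along(train_cases)) {
    if (!any(train_cases[[i]]$labels == 1L))
      stop("training case ", i, " has no scar nodes on the surface")
    tn <- make_training_set(train_cases[[i]]$mesh, train_cases[[i]]$labels,
                            seed = derive_seed(cfg$seed, 1000L + i))
    if (length(tn$nodes) > cfg$max_train_nodes) {
      keep <- with_seed(derive_seed(cfg$seed, 3000L + i),
                        sample(seq_along(tn$nodes), cfg$max_train_nodes))
      tn$nodes <- tn$nodes[keep]
      tn$labels <- tn$labels[keep]
    }
    train_cases[[i]]$train_nodes <- tn
    train_cases[[i]]$train_edges <- sample_edges(
      train_cases[[i]]$mesh, train_cases[[i]]$labels,
      seed = derive_seed(cfg$seed, 2000L + i),
      max_edges = cfg$max_train_edges)
  }

  say(cfg, "training unary network")
  tcfg <- cfg$train_t; tcfg$seed <- derive_seed(cfg$seed, 31L)
  theta_t <- init_t_net(cfg$msp, cfg$arch, seed = derive_seed(cfg$seed, 11L))
  theta_t <- train_t_net(t_provider(train_cases, cfg), theta_t, tcfg)

  theta_n <- NULL
  if (cfg$lambda > 0) {
    say(cfg, "training pairwise network")
    ncfg <- cfg$train_n; ncfg$seed <- derive_seed(cfg$seed, 32L)
    theta_n <- init_n_net(cfg$msp, cfg$arch, seed = derive_seed(cfg$seed, 12L))
    theta_n <- train_n_net(n_provider(train_cases, cfg), theta_n, ncfg)
  }

  rows <- NULL
  for (i in seq_along(test_cases)) {
    cs <- test_cases[[i]]
    case_id <- cfg$n_train + i
    say(cfg, "classifying test case ", case_id)
    res <- classify_scars(cs$image_norm, cs$mesh, theta_t, theta_n,
                          lambda = cfg$lambda)
    rows <- rbind(rows, metrics_row(case_id, "learngc",
                                    surface_metrics(res$labels, cs$labels),
                                    cs$dice_la))
    if (cfg$baselines) {
      rows <- rbind(rows, run_baselines(cfg, cs, case_id))
    }
  }
  summary <- stats::aggregate(
    cbind(accuracy, sensitivity, specificity, dice_scar, gdice) ~ method,
    data = rows, FUN = function(x) c(mean = mean(x), sd = stats::sd(x)),
    na.action = stats::na.pass)
  out <- structure(list(per_case = rows, summary = summary,
                        theta_t = theta_t, theta_n = theta_n, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    utils::write.csv(rows, file.path(cfg$out_dir, "per_case_metrics.csv"),
                     row.names = FALSE)
    writeLines(c(paste("seed", cfg$seed),
                 utils::capture.output(utils::str(cfg, max.level = 2))),
               file.path(cfg$out_dir, "provenance.txt"))
  }
  out
}

# The four classical baselines on one test case, evaluated on the manual-LA
# surface against ground truth projected on that same surface.
run_baselines <- function(cfg, cs, case_id) {
  truth <- cs$truth
  mesh_m <- if (cfg$use_auto_seg)
    extract_surface(truth$la_seg, truth$spacing, truth$origin,
                    smooth_iter = cfg$smooth_iter) else cs$mesh
  gt_m <- if (cfg$use_auto_seg)
    project_labels(image_volume(truth$scar_seg * 1, truth$spacing,
                                truth$origin), mesh_m,
                   depth_out_mm = cfg$depth_out_mm,
                   depth_in_mm = cfg$depth_in_mm) else cs$labels
  wall <- wall_from_la(truth$la_seg, cfg$wall_dilation_mm, truth$spacing)
  img <- truth$image
  model <- mgmm_fit(mask_values(img, wall), K_scar = cfg$mgmm_K_scar,
                    K_normal = cfg$mgmm_K_normal,
                    seed = derive_seed(cfg$seed, 40L + case_id))
  post <- array(0, dim(img$data))
  post[wall] <- mgmm_posterior(model, img$data[wall])
  masks <- list(
    `2sd` = threshold_nsd(img, wall, 2),
    otsu = threshold_otsu(img, wall),
    mgmm = wall & post >= 0.5,
    mgmm_gc = mgmm_gc(img, wall, model, lambda = 0.5))
  rows <- NULL
  for (nm in names(masks)) {
    lab <- project_labels(image_volume(masks[[nm]] * 1, truth$spacing,
                                       truth$origin), mesh_m,
                          depth_out_mm = cfg$depth_out_mm,
                          depth_in_mm = cfg$depth_in_mm)
    rows <- rbind(rows, metrics_row(case_id, nm,
                                    surface_metrics(lab, gt_m), cs$dice_la))
  }
  rows
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s Dice(scar) %.3f +/- %.3f | GDice %.3f | acc %.3f\n",
                s$method[i], s$dice_scar[i, "mean"], s$dice_scar[i, "sd"],
                s$gdice[i, "mean"], s$accuracy[i, "mean"]))
  }
  invisible(x)
}

#' Parameter study over one experiment axis
#'
#' Repeats [run_pipeline()] varying a single axis — `patch_size` (in-plane
#' width; the long axis is width + 4), `lambda`, `R` (random-shift range) or
#' `N_s` (number of scales) — with everything else, including the phantom
#' corpus, held fixed. Mirrors the parameter-study design of the method's
#' evaluation.
#'
#' @param cfg Base [experiment_config()].
#' @param axis One of `"patch_size"`, `"lambda"`, `"R"`, `"N_s"`.
#' @param values Numeric vector (length >= 2) of axis values.
#' @return Data frame with one row per value: mean and SD of the test
#'   Dice(scar) of the graph-cuts method, plus the axis value.
#' @export
run_parameter_study <- function(cfg, axis = c("patch_size", "lambda", "R",
                                              "N_s"), values) {
  axis <- match.arg(axis)
  if (length(values) < 2) stop("need at least 2 values for a study")
  rows <- NULL
  for (v in values) {
    cv <- cfg
    if (axis == "lambda") cv$lambda <- v
    else if (axis == "R")
      cv$msp <- msp_config(cfg$msp$dims, cfg$msp$n_scales,
                           cfg$msp$base_spacing_mm, shift_R_mm = v)
    else if (axis == "N_s")
      cv$msp <- msp_config(cfg$msp$dims, as.integer(v),
                           cfg$msp$base_spacing_mm, cfg$msp$shift_R_mm)
    else
      cv$msp <- msp_config(c(v, v, v + 4), cfg$msp$n_scales,
                           cfg$msp$base_spacing_mm, cfg$msp$shift_R_mm)
    res <- run_pipeline(cv)
    dice <- res$per_case$dice_scar[res$per_case$method == "learngc"]
    rows <- rbind(rows, data.frame(axis = axis, value = v,
                                   dice_scar_mean = mean(dice),
                                   dice_scar_sd = stats::sd(dice),
                                   n_cases = length(dice)))
  }
  rows
}
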
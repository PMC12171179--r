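## Clinical tabular statistics: group-difference screening, random-forest
## feature selection and the classical machine-learning baselines.

is_binary_col <- function(x) all(x %in% c(0, 1))

#' Screen clinical features for group differences
#'
#' Numeric features are compared between the two stenosis groups with a
#' two-sided Mann-Whitney U test (normal approximation with tie
#' correction, no continuity correction) and summarised as median (Q1, Q3);
#' binary features use a 2x2 chi-square test without continuity correction
#' and are summarised as positive counts. Raw p-values are reported,
#' together with a Benjamini-Hochberg adjusted column as a labelled
#' extension.
#'
#' @param clinical data.frame or matrix of features (rows = patients).
#' @param labels 0/1 group labels.
#' @return data.frame with one row per feature: `feature`, `test`
#'   (`mann_whitney_u` / `chi_square`), `statistic`, `p_value`, `p_adj_bh`,
#'   group summaries and a `degenerate` flag for constant features.
#' @export
compare_groups <- function(clinical, labels) {
  clinical <- as.data.frame(clinical)
  labels <- as.integer(labels)
  assert_that(sum(labels == 0) > 0 && sum(labels == 1) > 0,
              "both groups must be non-empty")
  rows <- lapply(names(clinical), function(f) {
    x <- clinical[[f]]
    x0 <- x[labels == 0]; x1 <- x[labels == 1]
    if (is_binary_col(x)) {
      degenerate <- length(unique(x)) < 2
      if (degenerate) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tab <- table(factor(x, levels = 0:1), factor(labels, levels = 0:1))
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      data.frame(feature = f, test = "chi_square", statistic = stat,
                 p_value = p,
                 summary0 = sum(x0 == 1), summary1 = sum(x1 == 1),
                 q1_0 = NA_real_, q3_0 = NA_real_, q1_1 = NA_real_,
                 q3_1 = NA_real_, degenerate = degenerate)
    } else {
      degenerate <- stats::sd(x) < 1e-12
      wt <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                                correct = FALSE))
      q0 <- stats::quantile(x0, c(0.25, 0.5, 0.75), names = FALSE)
      q1 <- stats::quantile(x1, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(feature = f, test = "mann_whitney_u",
                 statistic = unname(wt$statistic),
                 p_value = if (degenerate) NA_real_ else wt$p.value,
                 summary0 = q0[2], summary1 = q1[2],
                 q1_0 = q0[1], q3_0 = q0[3], q1_1 = q1[1], q3_1 = q1[3],
                 degenerate = degenerate)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Select the most important clinical features by random forest
#'
#' Fits a random forest on the supplied (training) rows and ranks features
#' by mean decrease in node impurity, normalised to sum to one; the top `k`
#' are selected for the clinical branch.
#'
#' @param clinical data.frame or matrix of features.
#' @param labels 0/1 labels.
#' @param k number of features to keep (default 15).
#' @param ntree forest size (default 500).
#' @param seed RNG seed (forest fitting is seed-deterministic).
#' @return list with `ranking` (data.frame `feature`, `importance`, sorted
#'   descending, ties broken by column order), `selected` (character vector
#'   of length `k`) and `k`.
#' @export
select_top_features <- function(clinical, labels, k = 15, ntree = 500,
                                seed = 1) {
  clinical <- as.data.frame(clinical)
  assert_that(k <= ncol(clinical),
              "k exceeds the number of available features")
  set.seed(seed)
  rf <- randomForest::randomForest(x = clinical,
                                   y = factor(labels, levels = 0:1),
                                   ntree = ntree)
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  ord <- top_k_idx(imp, length(imp))
  ranking <- data.frame(feature = names(clinical)[ord],
                        importance = unname(imp[ord]))
  list(ranking = ranking, selected = ranking$feature[seq_len(k)], k = k)
}

## per-mask colour summaries of one image: mean and sd of each RGB, HSV and
## L*a*b* channel
#' Colour summary parameters of one image over named region masks
#'
#' For each mask, the mean and standard deviation of every RGB, HSV and
#' CIELAB channel of the masked pixels -- the hand-crafted image descriptors
#' used by the classical baselines in place of learned embeddings.
#'
#' @param img `H x W x 3` array, 0-255.
#' @param masks named list of logical `H x W` masks.
#' @return named numeric vector (`<mask>_<channel>_<mean|sd>`).
#' @export
image_summary_features <- function(img, masks) {
  out <- c()
  for (mk in names(masks)) {
    m <- masks[[mk]]
    px <- rbind(img[, , 1][m], img[, , 2][m], img[, , 3][m])
    hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
    lab <- t(grDevices::convertColor(t(px) / 255, from = "sRGB", to = "Lab"))
    ch <- rbind(px / 255, hsv, lab)
    rownames(ch) <- c("r", "g", "b", "h", "s", "v", "L", "a", "B")
    stats <- c(apply(ch, 1, mean), apply(ch, 1, stats::sd))
    names(stats) <- paste0(mk, "_", rep(rownames(ch), 2),
                           rep(c("_mean", "_sd"), each = nrow(ch)))
    out <- c(out, stats)
  }
  out
}

#' Assemble the hand-crafted feature table for the classical baselines
#'
#' Concatenates, per patient: the 15 fiducial pulse parameters, colour
#' summaries of the tongue (whole body and coating region) and face
#' (forehead, nose, cheeks) region masks, and the top-`clinical_k`
#' random-forest-selected clinical features (screened on the train split).
#'
#' @param manifest a `cohort_manifest`.
#' @param image_size raster size for the image summaries.
#' @param clinical_k clinical features retained (default 15).
#' @param seed RNG seed for the screening forest.
#' @return list with `features` (data.frame, rownames = patient ids),
#'   `labels`, `splits`, `selected_clinical`.
#' @export
baseline_feature_table <- function(manifest, image_size = c(64, 64),
                                   clinical_k = 15, seed = 1) {
  rec <- manifest$records
  pf <- pulse_features_table(manifest)
  pm <- as.matrix(pf[, PULSE_FEATURE_NAMES])
  pm[is.na(pm)] <- 0
  tmk <- tongue_region_masks(image_size[1], image_size[2])
  fmk <- face_region_masks(image_size[1], image_size[2])
  fmk <- fmk[c("forehead", "nose", "cheek_left", "cheek_right")]
  img_rows <- t(vapply(seq_len(nrow(rec)), function(i) {
    tg <- read_image(file.path(manifest$root, rec$tongue_path[i]), image_size)
    fc <- read_image(file.path(manifest$root, rec$face_path[i]), image_size)
    c(image_summary_features(tg, tmk), image_summary_features(fc, fmk))
  }, numeric(18 * (length(tmk) + length(fmk)))))
  tab <- read_clinical_table(manifest)
  tab <- tab[rec$patient_id, manifest$features, drop = FALSE]
  tr <- which(rec$split == "train")
  sel <- select_top_features(tab[tr, , drop = FALSE], rec$label[tr],
                             k = clinical_k, seed = derive_seed(seed, "screen"))
  feats <- data.frame(pm, img_rows, as.matrix(tab[, sel$selected, drop = FALSE]),
                      check.names = TRUE)
  rownames(feats) <- rec$patient_id
  list(features = feats, labels = as.integer(rec$label), splits = rec$split,
       selected_clinical = sel$selected)
}

#' Classical machine-learning baselines
#'
#' Trains logistic regression, random forest, an RBF support vector
#' machine, k-nearest neighbours and gradient-boosted trees on the train
#' split of a feature table and evaluates each on the internal and external
#' splits with the same metrics as the fusion model. Hyper-parameters are
#' library-conventional defaults (RF 500 trees; SVM RBF with probability
#' outputs; KNN k = 5; boosting 100 rounds of depth 3) recorded in the
#' result's attributes.
#'
#' @param features data.frame of numeric features.
#' @param labels 0/1 labels.
#' @param splits character vector of `train`/`internal`/`external` tags.
#' @param seed RNG seed (per-model seeds are derived from it).
#' @return data.frame of evaluation rows (5 models x evaluated splits).
#' @export
run_baselines <- function(features, labels, splits, seed = 1) {
  features <- as.data.frame(features)
  assert_that(!anyNA(features), "feature table contains missing values")
  labels <- as.integer(labels)
  tr <- splits == "train"
  assert_that(sum(tr) > 0 && length(unique(labels[tr])) == 2,
              "train split must contain both classes")
  sc <- minmax_fit(as.matrix(features[tr, , drop = FALSE]))
  X <- as.data.frame(minmax_apply(as.matrix(features), sc))
  eval_splits <- intersect(c("internal", "external"), unique(splits))
  ytr <- factor(labels[tr], levels = 0:1)

  score_fun <- list(
    logistic_regression = function() {
      d <- cbind(X[tr, , drop = FALSE], .y = labels[tr])
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      function(newx) suppressWarnings(
        as.numeric(stats::predict(fit, newdata = newx, type = "response")))
    },
    random_forest = function() {
      fit <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = ytr,
                                        ntree = 500)
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    svm = function() {
      fit <- e1071::svm(x = as.matrix(X[tr, , drop = FALSE]), y = ytr,
                        kernel = "radial", probability = TRUE)
      function(newx) {
        pr <- stats::predict(fit, as.matrix(newx), probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    knn = function() {
      trx <- X[tr, , drop = FALSE]
      function(newx) {
        pr <- class::knn(trx, newx, cl = ytr, k = 5, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }
    },
    xgboost = function() {
      dtr <- xgboost::xgb.DMatrix(as.matrix(X[tr, , drop = FALSE]),
                                  label = labels[tr], nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 3, nthread = 1),
                                data = dtr, nrounds = 100, verbose = 0)
      function(newx) stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newx),
                                                              nthread = 1))
    })

  rows <- list()
  for (mn in names(score_fun)) {
    set.seed(derive_seed(seed, mn))
    scorer <- score_fun[[mn]]()
    for (sp in eval_splits) {
      idx <- splits == sp
      if (length(unique(labels[idx])) < 2) next
      p <- scorer(X[idx, , drop = FALSE])
      rows[[paste(mn, sp)]] <- eval_report_row(mn, sp, p, labels[idx])
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "hyperparameters") <- list(rf_ntree = 500, svm_kernel = "radial",
                                       knn_k = 5, xgb_nrounds = 100,
                                       xgb_max_depth = 3)
  out
}
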
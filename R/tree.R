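# Binary classification tree with the Gini impurity criterion, written out
# in full: exhaustive split search over midpoints of consecutive distinct
# feature values, recursive growth to a depth cap (default 2), majority-vote
# leaves. Everything is deterministic; ties in impurity decrease break
# toward the lower feature index and then the smaller threshold, and leaf
# ties break toward the aggressive class (favouring sensitivity in a safety
# application).

POSITIVE_CLASS <- "aggressive"

#' Gini impurity of class counts
#'
#' `1 - sum(p_i^2)` over class proportions; bounded by 0.5 for two classes.
#'
#' @param counts Nonnegative per-class counts, at least one positive.
#' @return Impurity in `[0, 1 - 1/k]`.
#' @export
gini <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) {
    stop("`counts` must be nonnegative with a positive total", call. = FALSE)
  }
  p <- counts / sum(counts)
  1 - sum(p^2)
}

tree_classes <- function(y) {
  cl <- sort(unique(y))
  # keep the positive class last so leaf tie-breaks can favour it
  if (POSITIVE_CLASS %in% cl) cl <- c(setdiff(cl, POSITIVE_CLASS), POSITIVE_CLASS)
  cl
}

class_counts <- function(y, classes) {
  vapply(classes, function(cl) sum(y == cl), numeric(1))
}

leaf_prediction <- function(counts) {
  # argmax; on ties the positive class wins when tied for the maximum
  best <- names(counts)[counts == max(counts)]
  if (POSITIVE_CLASS %in% best) POSITIVE_CLASS else best[1]
}

#' Best Gini split of a node
#'
#' Exhaustive search over every feature and every midpoint between
#' consecutive distinct sorted values, maximising the impurity decrease
#' `G(parent) - (nL/n G(left) + nR/n G(right))`. Rows with feature value
#' `<=` threshold go left.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class label vector, length `nrow(X)`.
#' @return A list `(feature_index, threshold, impurity_decrease)`, or
#'   `NULL` when no split decreases impurity.
#' @export
best_split <- function(X, y) {
  n <- nrow(X)
  if (n < 2L) return(NULL)
  classes <- tree_classes(y)
  parent <- gini(class_counts(y, classes))
  if (parent == 0) return(NULL)
  ybin <- y == POSITIVE_CLASS
  if (!any(ybin)) ybin <- y == classes[1]  # generic binary fallback
  n_pos <- sum(ybin)

  best <- NULL
  best_dec <- 1e-12  # floor guards fp noise on zero-decrease candidates
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    cum_pos <- cumsum(ybin[ord])
    boundary <- which(xs[-n] < xs[-1])  # split between distinct values
    if (!length(boundary)) next
    nl <- boundary
    pl <- cum_pos[boundary]
    gl <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
    nr <- n - nl
    pr <- n_pos - pl
    gr <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
    dec <- parent - (nl * gl + nr * gr) / n
    i_best <- which.max(dec)  # first max: smaller threshold on ties
    if (dec[i_best] > best_dec) {
      best_dec <- dec[i_best]
      b <- boundary[i_best]
      best <- list(feature_index = j,
                   threshold = (xs[b] + xs[b + 1]) / 2,
                   impurity_decrease = dec[i_best])
    }
  }
  best
}

build_node <- function(X, y, depth, max_depth, min_samples_split, classes) {
  counts <- class_counts(y, classes)
  make_leaf <- function() {
    list(leaf = TRUE, counts = counts, prediction = leaf_prediction(counts))
  }
  if (depth >= max_depth || length(y) < min_samples_split ||
      gini(counts) == 0) {
    return(make_leaf())
  }
  sp <- best_split(X, y)
  if (is.null(sp)) return(make_leaf())
  go_left <- X[, sp$feature_index] <= sp$threshold
  list(leaf = FALSE,
       feature_index = sp$feature_index,
       feature = colnames(X)[sp$feature_index] %||% NA_character_,
       threshold = sp$threshold,
       impurity_decrease = sp$impurity_decrease,
       counts = counts,
       left = build_node(X[go_left, , drop = FALSE], y[go_left],
                         depth + 1L, max_depth, min_samples_split, classes),
       right = build_node(X[!go_left, , drop = FALSE], y[!go_left],
                          depth + 1L, max_depth, min_samples_split, classes))
}

#' Fit a depth-capped Gini decision tree
#'
#' Recursively splits until the depth cap, node purity, or no improving
#' split. Fitting involves no randomness: repeated calls on the same data
#' agree exactly.
#'
#' @param X Numeric feature matrix.
#' @param y Class label vector (binary).
#' @param max_depth Maximum number of split levels (default 2).
#' @param min_samples_split Minimum node size to attempt a split.
#' @return An object of class `sbs_tree`.
#' @export
fit_tree <- function(X, y, max_depth = 2L, min_samples_split = 2L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("cannot fit a tree on an empty matrix", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  classes <- tree_classes(y)
  root <- build_node(X, y, 0L, max_depth, min_samples_split, classes)
  structure(list(root = root, classes = classes, n_features = ncol(X),
                 feature_names = colnames(X), max_depth = max_depth),
            class = "sbs_tree")
}

#' @export
print.sbs_tree <- function(x, ...) {
  describe <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf -> ", node$prediction, "  [",
          paste(names(node$counts), node$counts, sep = "=", collapse = ", "),
          "]\n", sep = "")
    } else {
      nm <- if (!is.na(node$feature)) node$feature
            else paste0("x", node$feature_index)
      cat(pad, nm, " <= ", signif(node$threshold, 5), "\n", sep = "")
      describe(node$left, indent + 1L)
      describe(node$right, indent + 1L)
    }
  }
  cat("<sbs_tree, max_depth ", x$max_depth, ">\n", sep = "")
  describe(x$root, 0L)
  invisible(x)
}

#' Predict classes with a fitted tree
#'
#' @param object An `sbs_tree`.
#' @param newdata Numeric feature matrix with the training feature count.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.sbs_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; tree was fitted on ",
         object$n_features, call. = FALSE)
  }
  route <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$feature_index] <= node$threshold) node$left
              else node$right
    }
    node$prediction
  }
  vapply(seq_len(nrow(newdata)), function(i) route(object$root, newdata[i, ]),
         character(1))
}

#' Gini-decrease feature importance
#'
#' Each split contributes its impurity decrease weighted by the fraction of
#' training samples reaching the node; contributions are summed per feature
#' and normalised to 1. A single-leaf tree has no splits: an all-zero
#' vector is returned with attribute `no_splits = TRUE`.
#'
#' @param tree An `sbs_tree`.
#' @return Named numeric vector of importances over the training features.
#' @export
feature_importance <- function(tree) {
  imp <- numeric(tree$n_features)
  n_root <- sum(tree$root$counts)
  walk <- function(node) {
    if (node$leaf) return(invisible())
    imp[node$feature_index] <<- imp[node$feature_index] +
      sum(node$counts) / n_root * node$impurity_decrease
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  names(imp) <- tree$feature_names %||% paste0("x", seq_along(imp))
  if (sum(imp) == 0) {
    attr(imp, "no_splits") <- TRUE
    return(imp)
  }
  imp / sum(imp)
}

#' Stratified (or participant-grouped) train/test split
#'
#' Default: segment-level stratified random split that preserves class
#' proportions within one row per class (largest-remainder allocation of
#' `round(train_frac * n)` training rows). With `group_ids`, whole groups
#' (e.g. participants) are assigned to one side, preventing leakage from
#' overlapping windows of the same recording.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param train_frac Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @param stratified Stratify by class (ignored when `group_ids` given).
#' @param group_ids Optional per-row grouping factor for group-wise splits.
#' @return List with `train` and `test`, each `(X, y, idx)`.
#' @export
split_data <- function(X, y, train_frac = 0.7, seed = 1L, stratified = TRUE,
                       group_ids = NULL) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must lie strictly between 0 and 1", call. = FALSE)
  }
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  if (!is.null(group_ids)) {
    groups <- unique(group_ids)
    groups <- sample(groups)
    sizes <- vapply(groups, function(g) sum(group_ids == g), numeric(1))
    n_train_target <- round(train_frac * n)
    take <- cumsum(sizes) <= n_train_target
    if (!any(take)) take[1] <- TRUE
    idx_train <- which(group_ids %in% groups[take])
  } else if (stratified) {
    n_train_target <- round(train_frac * n)
    classes <- tree_classes(y)
    per_class <- lapply(classes, function(cl) which(y == cl))
    exact <- vapply(per_class, length, numeric(1)) * train_frac
    base <- floor(exact)
    rem <- n_train_target - sum(base)
    if (rem > 0) {
      order_rem <- order(exact - base, decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
    }
    idx_train <- sort(unlist(mapply(function(idx, k) sample(idx, k),
                                    per_class, base, SIMPLIFY = FALSE)))
  } else {
    idx_train <- sort(sample.int(n, round(train_frac * n)))
  }
  idx_test <- setdiff(seq_len(n), idx_train)
  for (side in list(idx_train, idx_test)) {
    miss <- setdiff(unique(y), unique(y[side]))
    if (length(miss)) {
      warning("class absent from one side of the split: ",
              paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  list(train = list(X = X[idx_train, , drop = FALSE], y = y[idx_train],
                    idx = idx_train),
       test = list(X = X[idx_test, , drop = FALSE], y = y[idx_test],
                   idx = idx_test))
}

node_to_list <- function(node) {
  if (node$leaf) {
    list(counts = as.list(node$counts), class = node$prediction)
  } else {
    list(feature = node$feature_index, threshold = node$threshold,
         impurity_decrease = node$impurity_decrease,
         counts = as.list(node$counts),
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(x) {
  if (!is.null(x$class)) {
    list(leaf = TRUE, counts = unlist(x$counts), prediction = x$class)
  } else {
    list(leaf = FALSE, feature_index = x$feature,
         feature = NA_character_, threshold = x$threshold,
         impurity_decrease = x$impurity_decrease,
         counts = unlist(x$counts),
         left = node_from_list(x$left), right = node_from_list(x$right))
  }
}

#' Serialise a tree to JSON
#' @param tree An `sbs_tree`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  doc <- list(max_depth = tree$max_depth, classes = tree$classes,
              n_features = tree$n_features,
              feature_names = tree$feature_names,
              root = node_to_list(tree$root))
  if (is.null(path)) {
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a tree from JSON
#' @param x A path to, or string of, JSON written by [tree_to_json()].
#' @return An `sbs_tree`.
#' @export
tree_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  structure(list(root = node_from_list(doc$root),
                 classes = unlist(doc$classes),
                 n_features = doc$n_features,
                 feature_names = if (is.null(doc$feature_names)) NULL
                                 else unlist(doc$feature_names),
                 max_depth = doc$max_depth),
            class = "sbs_tree")
}
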
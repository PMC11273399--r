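# Unified second-order tree builder. CART with variance impurity is the
# special case g = -(y), h = 1, lambda = 0: the Newton leaf -G/(H+lambda)
# becomes the node mean and the split gain is proportional to the SSE
# reduction. Boosted trees pass loss gradients/hessians and regularizers.
#
# Tie-breaking is deterministic: features are scanned in ascending index
# order and thresholds in ascending value order; a split is adopted only if
# its gain strictly exceeds the incumbent's.
build_tree_core <- function(X, g, h, lambda = 0, gamma = 0,
                            max_depth = Inf, min_leaf = 1L,
                            features_per_split = 1) {
  n <- nrow(X)
  d <- ncol(X)
  n_feat <- max(1L, min(d, floor(features_per_split * d)))
  nodes <- list()

  leaf_node <- function(idx) {
    G <- sum(g[idx]); H <- sum(h[idx])
    list(leaf = TRUE, value = -G / (H + lambda), n = length(idx))
  }

  best_split <- function(idx, feats) {
    G <- sum(g[idx]); H <- sum(h[idx])
    parent <- G^2 / (H + lambda)
    best <- NULL
    for (f in feats) {
      xs <- X[idx, f]
      ord <- order(xs, method = "radix")
      xs <- xs[ord]
      cg <- cumsum(g[idx][ord])
      ch <- cumsum(h[idx][ord])
      m <- length(xs)
      pos <- which(xs[-m] < xs[-1]) # split after position pos
      if (min_leaf > 1)
        pos <- pos[pos >= min_leaf & (m - pos) >= min_leaf]
      if (length(pos) == 0) next
      gl <- cg[pos]; hl <- ch[pos]
      gain <- 0.5 * (gl^2 / (hl + lambda) +
                       (G - gl)^2 / (H - hl + lambda) - parent) - gamma
      k <- which.max(gain) # first max: lowest threshold wins ties
      if (is.null(best) || gain[k] > best$gain) {
        best <- list(gain = gain[k], feature = f,
                     threshold = (xs[pos[k]] + xs[pos[k] + 1]) / 2,
                     left = idx[ord[seq_len(pos[k])]],
                     right = idx[ord[(pos[k] + 1):m]])
      }
    }
    best
  }

  grow <- function(idx, depth) {
    if (depth >= max_depth || length(idx) < 2L * min_leaf || length(idx) < 2L) {
      nodes[[length(nodes) + 1L]] <<- leaf_node(idx)
      return(length(nodes))
    }
    feats <- if (n_feat < d) sort(sample.int(d, n_feat)) else seq_len(d)
    sp <- best_split(idx, feats)
    if (is.null(sp) || sp$gain <= 0) {
      nodes[[length(nodes) + 1L]] <<- leaf_node(idx)
      return(length(nodes))
    }
    me <- length(nodes) + 1L
    nodes[[me]] <<- list(leaf = FALSE) # reserve slot
    li <- grow(sp$left, depth + 1L)
    ri <- grow(sp$right, depth + 1L)
    nodes[[me]] <<- list(leaf = FALSE, feature = sp$feature,
                         threshold = sp$threshold, left = li, right = ri,
                         n = length(idx))
    me
  }

  root <- grow(seq_len(n), 0L)
  list(nodes = nodes, root = root)
}

predict_tree_core <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(node_id, idx) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      out[idx] <<- node$value
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) recurse(node$left, idx[go_left])
    if (any(!go_left)) recurse(node$right, idx[!go_left])
  }
  if (nrow(X) > 0) recurse(tree$root, seq_len(nrow(X)))
  out
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  df <- as.data.frame(x)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("features must be numeric", call. = FALSE)
  m <- data.matrix(df)
  storage.mode(m) <- "double"
  m
}

check_xy <- function(x, y) {
  X <- as_feature_matrix(x)
  if (nrow(X) != length(y)) stop("row counts of `x` and `y` differ", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  X
}

new_model <- function(fit, subclass, method, feature_names) {
  structure(c(fit, list(method = method, feature_names = feature_names)),
            class = c(paste0("pigwt_", subclass), "pigwt_model"))
}

model_matrix <- function(object, newdata) {
  X <- as_feature_matrix(newdata)
  fn <- object$feature_names
  if (!is.null(colnames(X)) && !is.null(fn)) {
    if (!all(fn %in% colnames(X)))
      stop("newdata is missing features: ",
           paste(setdiff(fn, colnames(X)), collapse = ", "), call. = FALSE)
    X <- X[, fn, drop = FALSE]
  } else if (ncol(X) != length(fn)) {
    stop(sprintf("expected %d features, got %d", length(fn), ncol(X)), call. = FALSE)
  }
  X
}

#' Fit a single regression tree
#'
#' Greedy top-down induction with variance-reduction impurity (the
#' regression analogue of information gain): every node takes the
#' (feature, midpoint-threshold) split that maximally reduces the sum of
#' squared errors, with deterministic tie-breaking (lowest feature index,
#' then lowest threshold). Leaves predict the node mean.
#'
#' @param x Feature data frame or matrix.
#' @param y Numeric response (weights in kg for the weight models).
#' @param max_depth Maximum tree depth (`Inf` = grow until pure).
#' @param min_samples_leaf Minimum rows in each leaf.
#' @param features_per_split Fraction of features considered at each split
#'   (1 = all; < 1 samples them, as in a random forest).
#' @param seed Seed for feature subsampling (only relevant when
#'   `features_per_split < 1`).
#' @return An object of class `pigwt_tree` / `pigwt_model`.
#' @examples
#' fit <- fit_tree(data.frame(x = 1:8), y = c(1, 1, 1, 1, 2, 2, 2, 2),
#'                 max_depth = 1)
#' predict(fit, data.frame(x = c(2, 7)))
#' @export
fit_tree <- function(x, y, max_depth = Inf, min_samples_leaf = 1,
                     features_per_split = 1, seed = NULL) {
  X <- check_xy(x, y)
  if (nrow(X) < 1) stop("empty training data", call. = FALSE)
  tree <- local_seed(seed, build_tree_core(
    X, g = -y, h = rep(1, length(y)), lambda = 0, gamma = 0,
    max_depth = max_depth, min_leaf = as.integer(min_samples_leaf),
    features_per_split = features_per_split
  ))
  new_model(list(tree = tree), "tree", "tree", colnames(X))
}

#' @export
predict.pigwt_tree <- function(object, newdata, ...) {
  predict_tree_core(object$tree, model_matrix(object, newdata))
}
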
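# portable JSON dumps for the native models (tree dumps / coefficient dumps)

tree_to_df <- function(tree) {
  rows <- lapply(seq_along(tree$nodes), function(i) {
    n <- tree$nodes[[i]]
    data.frame(id = i, leaf = n$leaf,
               value = if (n$leaf) n$value else NA_real_,
               feature = if (n$leaf) NA_integer_ else n$feature,
               threshold = if (n$leaf) NA_real_ else n$threshold,
               left = if (n$leaf) NA_integer_ else n$left,
               right = if (n$leaf) NA_integer_ else n$right)
  })
  df <- do.call(rbind, rows)
  df$root <- tree$root
  df
}

df_to_tree <- function(df) {
  nodes <- lapply(seq_len(nrow(df)), function(i) {
    if (df$leaf[i]) list(leaf = TRUE, value = df$value[i])
    else list(leaf = FALSE, feature = df$feature[i], threshold = df$threshold[i],
              left = df$left[i], right = df$right[i])
  })
  list(nodes = nodes, root = df$root[1])
}

#' Serialize a fitted model to portable JSON
#'
#' Native models (tree, forest, boosted trees, Adaboost, LR, Lasso, KRR,
#' Stacking, and [fit_correction()] objects) are dumped as JSON trees /
#' coefficient tables with their feature lists and metadata, readable by any
#' JSON consumer. The SVR/MLP/BP adapters wrap third-party fits and are not
#' covered.
#'
#' @param model A `pigwt_model` or `pigwt_correction` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- serialize_model(model)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

serialize_model <- function(model) {
  if (inherits(model, "pigwt_correction")) {
    return(list(type = "correction", inputs = model$inputs,
                hyperparams = model$hyperparams, seed = model$seed,
                camera_height_cm = model$camera_height_cm,
                model_bl = serialize_model(model$model_bl),
                model_hw = serialize_model(model$model_hw),
                model_hdep = serialize_model(model$model_hdep)))
  }
  stopifnot(inherits(model, "pigwt_model"))
  base <- list(method = model$method, feature_names = model$feature_names)
  if (inherits(model, "pigwt_tree")) {
    c(base, list(type = "tree", tree = tree_to_df(model$tree)))
  } else if (inherits(model, "pigwt_forest")) {
    c(base, list(type = "forest", trees = lapply(model$trees, tree_to_df)))
  } else if (inherits(model, "pigwt_gboost")) {
    c(base, list(type = "gboost", base_score = model$base_score,
                 shrinkage = model$shrinkage, lambda = model$lambda,
                 gamma = model$gamma, rounds = model$rounds,
                 trees = lapply(model$trees, tree_to_df)))
  } else if (inherits(model, "pigwt_adaboost")) {
    c(base, list(type = "adaboost", log_inv_beta = model$log_inv_beta,
                 trees = lapply(model$trees, tree_to_df)))
  } else if (inherits(model, "pigwt_lr")) {
    c(base, list(type = "lr", coef = as.list(model$coef)))
  } else if (inherits(model, "pigwt_lasso")) {
    c(base, list(type = "lasso", coef = as.list(model$coef),
                 penalty = model$penalty))
  } else if (inherits(model, "pigwt_krr")) {
    c(base, list(type = "krr", alpha = model$alpha, Z = model$Z,
                 mu = model$mu, sg = model$sg, ym = model$ym,
                 kernel = model$kernel, gamma = model$gamma,
                 penalty = model$penalty))
  } else if (inherits(model, "pigwt_stacking")) {
    c(base, list(type = "stacking",
                 bases = lapply(model$bases, serialize_model),
                 meta = list(coef = as.list(model$meta$coef))))
  } else {
    stop("model type '", class(model)[1],
         "' wraps a third-party fit and has no portable JSON dump", call. = FALSE)
  }
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(if (file.exists(json[1])) json else json,
                          simplifyDataFrame = TRUE)
  deserialize_model(x)
}

deserialize_model <- function(x) {
  if (x$type == "correction") {
    return(structure(list(
      model_bl = deserialize_model(x$model_bl),
      model_hw = deserialize_model(x$model_hw),
      model_hdep = deserialize_model(x$model_hdep),
      inputs = x$inputs, hyperparams = x$hyperparams, seed = x$seed,
      camera_height_cm = x$camera_height_cm), class = "pigwt_correction"))
  }
  fn <- x$feature_names
  trees_of <- function(tl) {
    if (is.data.frame(tl)) list(df_to_tree(tl)) else lapply(tl, df_to_tree)
  }
  switch(x$type,
    tree = new_model(list(tree = df_to_tree(x$tree)), "tree", x$method, fn),
    forest = new_model(list(trees = trees_of(x$trees),
                            n_trees = length(x$trees)), "forest", x$method, fn),
    gboost = new_model(list(trees = trees_of(x$trees),
                            base_score = x$base_score, shrinkage = x$shrinkage,
                            lambda = x$lambda, gamma = x$gamma,
                            rounds = x$rounds), "gboost", x$method, fn),
    adaboost = new_model(list(trees = trees_of(x$trees),
                              log_inv_beta = x$log_inv_beta),
                         "adaboost", x$method, fn),
    lr = new_model(list(coef = unlist(x$coef)), "lr", x$method, fn),
    lasso = new_model(list(coef = unlist(x$coef), penalty = x$penalty),
                      "lasso", x$method, fn),
    krr = new_model(list(alpha = x$alpha, Z = as.matrix(x$Z), mu = x$mu,
                         sg = x$sg, ym = x$ym, kernel = x$kernel,
                         gamma = x$gamma, penalty = x$penalty),
                    "krr", x$method, fn),
    stacking = new_model(list(bases = lapply(x$bases, deserialize_model),
                              meta = list(coef = unlist(x$meta$coef))),
                         "stacking", x$method, fn),
    stop("unknown model dump type: ", x$type, call. = FALSE)
  )
}
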
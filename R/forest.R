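#' Bootstrap resample of a training table
#'
#' Draws `nrow(data)` instances with replacement using the current RNG
#' stream. Inside [train_forest()] this is the first draw made for each
#' tree, followed by its feature subset.
#'
#' @param data A data frame of training instances (>= 1 row).
#' @return List with `data` (the resample, as a tibble) and `indices`
#'   (the drawn row indices).
#' @export
bootstrap_sample <- function(data) {
  n <- nrow(data)
  if (is.null(n) || n < 1L) abort("cannot bootstrap an empty dataset")
  idx <- sample.int(n, n, replace = TRUE)
  list(data = tibble::as_tibble(data[idx, , drop = FALSE]), indices = idx)
}

#' Random feature subset
#'
#' `m` distinct feature indices drawn uniformly without replacement from
#' `1:M`, returned sorted.
#'
#' @param M Total feature count.
#' @param m Subset size, `1 <= m <= M`.
#' @return Sorted integer vector of length `m`.
#' @export
select_features <- function(M, m) {
  check_number(M, "M", min = 1)
  check_number(m, "m", min = 1, max = M)
  sort(sample.int(M, m))
}

gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split of (x, y) over the candidate feature columns.
# Candidate thresholds are midpoints between consecutive distinct sorted
# values; ties in impurity gain break to the lowest feature index, then the
# lowest threshold. Returns NULL when no feature separates the rows.
best_split <- function(x, y, features, n_classes) {
  n <- length(y)
  yi <- as.integer(y)
  parent <- gini(tabulate(yi, n_classes))
  best <- NULL
  eps <- 1e-12
  for (f in features) {
    v <- x[, f]
    ord <- order(v)
    vs <- v[ord]
    ys <- yi[ord]
    cut_at <- which(vs[-n] < vs[-1])       # positions between distinct values
    if (!length(cut_at)) next
    ind <- matrix(0L, nrow = n, ncol = n_classes)
    ind[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(ind, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
    left_n <- cut_at
    right_n <- n - cut_at
    left_counts <- cum[cut_at, , drop = FALSE]
    total <- cum[n, ]
    right_counts <- sweep(-left_counts, 2, total, `+`)
    g_left <- 1 - rowSums((left_counts / left_n)^2)
    g_right <- 1 - rowSums((right_counts / right_n)^2)
    gain <- parent - (left_n * g_left + right_n * g_right) / n
    bi <- which(gain >= max(gain) - eps)[1]  # lowest threshold among ties
    cand_gain <- gain[bi]
    if (is.null(best) || cand_gain > best$gain + eps) {
      best <- list(feature = f,
                   threshold = (vs[cut_at[bi]] + vs[cut_at[bi] + 1]) / 2,
                   gain = cand_gain)
    }
  }
  best
}

majority_label <- function(y, n_classes) {
  counts <- tabulate(as.integer(y), n_classes)
  which.max(counts)  # ties break to the lowest class in fixed label order
}

#' Grow one fully-grown decision tree
#'
#' Recursive binary splitting on Gini impurity over the assigned feature
#' subset only. Candidate thresholds are midpoints between consecutive
#' distinct sorted values. Trees are grown fully, with no pruning: a node
#' becomes a leaf only when it is pure or when no assigned feature separates
#' its rows (conflicting duplicates take the majority label). A separating
#' split is taken even at zero impurity gain, so parity-style label
#' structure is still resolved deeper down. All tie-breaks are
#' deterministic: lowest feature index, then lowest threshold, then lowest
#' class in the fixed label order.
#'
#' @param x Numeric matrix (rows = instances).
#' @param y Factor of labels, one per row; its level order is the fixed
#'   class order used for tie-breaking.
#' @param features Integer column indices the tree may split on (defaults to
#'   all columns).
#' @return An object of class `plm_tree`: a node tibble (`id`, `leaf`,
#'   `feature`, `threshold`, `left`, `right`, `label`) with attributes
#'   `features` and `classes`. Rows with `x[, feature] <= threshold` go
#'   left.
#' @export
grow_tree <- function(x, y, features = seq_len(ncol(x))) {
  x <- as.matrix(x)
  if (!is.factor(y)) y <- factor(y)
  if (nrow(x) < 1L) abort("cannot grow a tree on an empty sample")
  stopifnot(nrow(x) == length(y))
  classes <- levels(y)
  n_classes <- length(classes)
  nodes <- new.env(parent = emptyenv())
  nodes$rows <- list()
  add_node <- function(node) {
    id <- length(nodes$rows) + 1L
    nodes$rows[[id]] <- c(list(id = id), node)
    id
  }
  grow <- function(idx) {
    yy <- y[idx]
    if (length(unique(yy)) == 1L) {
      return(add_node(list(leaf = TRUE, feature = NA_character_,
                           threshold = NA_real_, left = NA_integer_,
                           right = NA_integer_,
                           label = classes[as.integer(yy[1])])))
    }
    sp <- best_split(x[idx, , drop = FALSE], yy, features, n_classes)
    if (is.null(sp)) {
      return(add_node(list(leaf = TRUE, feature = NA_character_,
                           threshold = NA_real_, left = NA_integer_,
                           right = NA_integer_,
                           label = classes[majority_label(yy, n_classes)])))
    }
    id <- add_node(list(leaf = FALSE, feature = colnames(x)[sp$feature],
                        threshold = sp$threshold, left = NA_integer_,
                        right = NA_integer_, label = NA_character_))
    go_left <- x[idx, sp$feature] <= sp$threshold
    left_id <- grow(idx[go_left])
    right_id <- grow(idx[!go_left])
    nodes$rows[[id]]$left <- left_id
    nodes$rows[[id]]$right <- right_id
    id
  }
  grow(seq_len(nrow(x)))
  tbl <- dplyr::bind_rows(lapply(nodes$rows, tibble::as_tibble))
  structure(tbl, class = c("plm_tree", class(tbl)),
            features = features, classes = classes)
}

predict_tree <- function(tree, x) {
  x <- as.matrix(x)
  leaf <- tree$leaf; feat <- tree$feature; thr <- tree$threshold
  left <- tree$left; right <- tree$right; lab <- tree$label
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    node <- 1L
    while (!leaf[node]) {
      node <- if (x[i, feat[node]] <= thr[node]) left[node] else right[node]
    }
    out[i] <- lab[node]
  }
  out
}

#' Train a random forest posture classifier
#'
#' From-scratch random forest: for each of `trees` members, draw a bootstrap
#' resample of the training rows, draw a random subset of `mtry` features,
#' and grow a fully-grown unpruned Gini tree ([grow_tree()]) on that
#' resample restricted to that subset. Prediction is by majority vote across
#' the ensemble. All randomness comes from one seeded stream with a fixed
#' draw order (per tree: bootstrap indices, then feature subset), so a
#' forest is bit-reproducible from `(data, trees, mtry, seed)`.
#'
#' @param data Training table: feature columns plus a label column.
#' @param label_col Name of the label column (default `"label"`).
#' @param features Feature column names (default: all numeric columns except
#'   the label).
#' @param trees Ensemble size `T` (default 10).
#' @param mtry Features per tree `m`; default `ceiling(sqrt(M))`.
#' @param seed RNG seed.
#' @param bootstrap Set `FALSE` to train every tree on the full sample
#'   (degenerate-forest test hook).
#' @return An object of class `plm_forest`.
#' @export
#' @examples
#' d <- tibble::tibble(a = c(0, 1, 2, 3), b = c(1, 1, 0, 0),
#'                     label = c("A", "A", "B", "B"))
#' fit <- train_forest(d, trees = 3, seed = 1)
#' predict(fit, d)
train_forest <- function(data, label_col = "label", features = NULL,
                         trees = 10, mtry = NULL, seed = 1L,
                         bootstrap = TRUE) {
  data <- tibble::as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, label_col)
  }
  if (!length(features) || !all(features %in% names(data))) {
    abort("no valid feature columns")
  }
  check_number(trees, "trees", min = 1)
  M <- length(features)
  if (is.null(mtry)) mtry <- ceiling(sqrt(M))
  check_number(mtry, "mtry", min = 1, max = M)
  x <- as.matrix(data[, features])
  y <- data[[label_col]]
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  n <- nrow(x)
  if (n < 1L) abort("cannot train on an empty dataset")

  members <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(trees), function(t) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      subset <- select_features(M, mtry)
      tree <- grow_tree(x[idx, , drop = FALSE], y[idx], subset)
      list(tree = tree, features = subset)
    })
  })
  structure(
    list(members = members, feature_names = features, classes = levels(y),
         trees = as.integer(trees), mtry = as.integer(mtry), M = M, n = n,
         seed = as.integer(seed)),
    class = "plm_forest"
  )
}

#' @export
print.plm_forest <- function(x, ...) {
  cat("<plm_forest>", x$trees, "fully-grown trees,", x$mtry, "of", x$M,
      "features per tree,", length(x$classes), "classes, n =", x$n, "\n")
  invisible(x)
}

forest_feature_matrix <- function(forest, newdata) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != forest$M) {
      abort(paste0("feature vector must have length ", forest$M))
    }
    m <- matrix(newdata, nrow = 1,
                dimnames = list(NULL, forest$feature_names))
    return(m)
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(forest$feature_names, names(newdata))
  if (length(missing)) {
    abort(paste0("newdata lacks feature column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as.matrix(newdata[, forest$feature_names, drop = FALSE])
}

#' Predict postures with a trained forest
#'
#' Each tree votes through its own feature subset; the winning class has the
#' maximal vote count, with ties broken to the lowest class in the fixed
#' label order. Vote counts always sum to the ensemble size.
#'
#' @param object A [train_forest()] fit.
#' @param newdata Feature table (or a single numeric feature vector).
#' @param type `"class"` for labels, `"votes"` for the per-class tally.
#' @param ... Unused.
#' @return For `"class"`, a character vector; for `"votes"`, a tibble with
#'   `.pred` and one count column per class.
#' @export
predict.plm_forest <- function(object, newdata, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  x <- forest_feature_matrix(object, newdata)
  preds <- vapply(object$members,
                  function(mem) predict_tree(mem$tree, x),
                  character(nrow(x)))
  preds <- matrix(preds, nrow = nrow(x))
  counts <- t(apply(preds, 1, function(p) {
    tabulate(match(p, object$classes), length(object$classes))
  }))
  if (length(object$classes) == 1L) counts <- matrix(counts, ncol = 1L)
  colnames(counts) <- object$classes
  winner <- object$classes[apply(counts, 1, which.max)]
  if (type == "class") return(winner)
  dplyr::bind_cols(tibble::tibble(.pred = winner), tibble::as_tibble(counts))
}

#' Single-instance prediction with its vote tally
#'
#' @param forest A [train_forest()] fit.
#' @param x A feature vector of length M (or one-row feature table).
#' @return List with `label` and `tally` (tibble `class`, `votes`).
#' @export
forest_predict <- function(forest, x) {
  votes <- predict(forest, x, type = "votes")
  tally <- tibble::tibble(class = forest$classes,
                          votes = as.integer(votes[1, forest$classes]))
  list(label = votes$.pred[1], tally = tally)
}

tree_depth <- function(tree, node = 1L) {
  row <- tree[node, ]
  if (row$leaf) return(1L)
  1L + max(tree_depth(tree, row$left), tree_depth(tree, row$right))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-tree summary of a forest
#'
#' @param x A `plm_forest`.
#' @param ... Unused.
#' @return A tibble with one row per tree: node/leaf counts, depth and the
#'   assigned feature subset.
#' @method tidy plm_forest
#' @export
tidy.plm_forest <- function(x, ...) {
  purrr::imap_dfr(x$members, function(mem, i) {
    tibble::tibble(
      tree = i,
      n_nodes = nrow(mem$tree),
      n_leaves = sum(mem$tree$leaf),
      depth = tree_depth(mem$tree),
      features = paste(x$feature_names[mem$features], collapse = ",")
    )
  })
}

#' One-row summary of a forest fit
#'
#' @param x A `plm_forest`.
#' @param ... Unused.
#' @return A one-row tibble: `trees`, `mtry`, `n_features`, `n_obs`,
#'   `n_classes`.
#' @method glance plm_forest
#' @export
glance.plm_forest <- function(x, ...) {
  tibble::tibble(trees = x$trees, mtry = x$mtry, n_features = x$M,
                 n_obs = x$n, n_classes = length(x$classes))
}
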
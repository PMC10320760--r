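#' Enumerate residue-set features
#'
#' The feature space for tree fitting: for each variable motif position (a1,
#' a2, X) and each nonempty residue set of size up to `max_set_size`, a binary
#' feature indicating whether the motif's residue at that position lies in the
#' set. Size-1 sets reproduce plain one-hot encoding. Enumeration is
#' position-major (a1, then a2, then X); within a position, sets are ordered
#' by size and then lexicographically, so feature indices are deterministic
#' and tie-breaks during tree fitting are reproducible.
#'
#' With `max_set_size = 5` this yields 3 * sum(choose(20, 1:5)) = 65,097
#' features.
#'
#' @param max_set_size Maximum residue-set size, 1..20 (default 5).
#' @return List of feature specs, each `list(position =, residues =)`, with
#'   attribute `labels` (human-readable).
#' @export
enumerate_features <- function(max_set_size = 5L) {
  stopifnot(max_set_size >= 1L, max_set_size <= 20L)
  sets <- list()
  for (k in seq_len(max_set_size)) {
    cm <- combn(AA_ALPHABET20, k, simplify = FALSE)
    sets <- c(sets, cm)
  }
  specs <- list()
  for (pos in c("a1", "a2", "x")) {
    specs <- c(specs, lapply(sets, function(s) list(position = pos, residues = s)))
  }
  attr(specs, "labels") <- vapply(specs, feature_label, "")
  specs
}

feature_label <- function(spec) {
  paste0(spec$position, " in {", paste(spec$residues, collapse = ","), "}")
}

#' Encode motifs against feature specs
#'
#' @param motifs Character vector of motifs.
#' @param specs Feature list from [enumerate_features()] (or a subset).
#' @return Integer 0/1 matrix, `length(motifs)` x `length(specs)`, columns
#'   named by feature label. Note the full 8,000 x 65,097 matrix is ~4 GB;
#'   for full-space fitting use [fit_caax_tree()], which never materializes
#'   it.
#' @export
encode <- function(motifs, specs) {
  p <- motif_parts(motifs)
  X <- matrix(0L, nrow = length(motifs), ncol = length(specs),
              dimnames = list(motifs, vapply(specs, feature_label, "")))
  for (j in seq_along(specs)) {
    X[, j] <- as.integer(p[[specs[[j]]$position]] %in% specs[[j]]$residues)
  }
  X
}

#' Binarize EF values into training labels
#'
#' Motifs with EF strictly above the threshold are labelled positive
#' (selection-enriched, prenylation-proficient), the rest negative. The
#' threshold is a required modelling choice and is recorded in the result.
#'
#' @param ef An `ef_table`.
#' @param threshold EF threshold (default 1.0: enriched vs depleted).
#' @return List of class `labeled_motifs`: `motifs`, `label` (integer 0/1),
#'   `threshold`.
#' @export
binarize_labels <- function(ef, threshold = 1.0) {
  structure(list(motifs = ef$motif,
                 label = as.integer(ef$ef > threshold),
                 threshold = threshold),
            class = "labeled_motifs")
}

entropy_bits <- function(pos, n) {
  p <- ifelse(n > 0, pos / n, 0)
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

# Pick the best split given per-feature counts at a node.
# n, pos: node totals; n1, pos1: per-feature totals where the feature is 1.
# Children must each hold >= min_samples. Returns NULL when no split gains.
best_split <- function(n, pos, n1, pos1, min_samples) {
  n0 <- n - n1
  pos0 <- pos - pos1
  h_parent <- entropy_bits(pos, n)
  gain <- h_parent - (n1 / n) * entropy_bits(pos1, n1) -
    (n0 / n) * entropy_bits(pos0, n0)
  gain[n1 < min_samples | n0 < min_samples] <- -Inf
  j <- unname(which.max(gain))
  if (!is.finite(gain[j]) || gain[j] <= 1e-12) return(NULL)
  list(feature = j, gain = unname(gain[j]))
}

grow_node <- function(depth, idx_info, max_depth, min_samples, counter_env,
                      split_fun, node_stats) {
  st <- node_stats(idx_info)
  node <- list(n = st$n, n_pos = st$pos, n_neg = st$n - st$pos,
               depth = depth,
               class = if (st$pos * 2L >= st$n) "positive" else "negative")
  if (depth >= max_depth || st$pos == 0L || st$pos == st$n) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- split_fun(idx_info)
  if (is.null(sp)) {
    node$leaf <- TRUE
    return(node)
  }
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$gain <- sp$gain
  node$left <- grow_node(depth + 1L, sp$idx0, max_depth, min_samples,
                         counter_env, split_fun, node_stats)
  node$right <- grow_node(depth + 1L, sp$idx1, max_depth, min_samples,
                          counter_env, split_fun, node_stats)
  node
}

#' Fit an entropy-based binary decision tree on a feature matrix
#'
#' Greedy binary splitting: at each node the feature maximizing the
#' information gain `H(parent) - sum (n_child/n) H(child)` (entropy in bits)
#' is chosen; splitting stops when the depth limit binds, a node is pure, no
#' split keeps both children at `min_samples` or more, or no feature gains.
#' Ties are broken by the first feature in column order.
#'
#' @param X Binary (0/1) feature matrix.
#' @param y Binary labels (0/1) of length `nrow(X)`.
#' @param max_depth Maximum depth, root = 0 (default 3).
#' @param min_samples Minimum motifs per node, applied to every node including
#'   internal ones (default 50).
#' @param specs Optional feature specs matching the columns of `X`, used for
#'   rule rendering.
#' @return Object of class `caax_tree`.
#' @export
fit_tree <- function(X, y, max_depth = 3L, min_samples = 50L, specs = NULL) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  y <- as.integer(y)
  split_fun <- function(idx) {
    n <- length(idx)
    pos <- sum(y[idx])
    Xi <- X[idx, , drop = FALSE]
    n1 <- colSums(Xi)
    pos1 <- colSums(Xi * y[idx])
    sp <- best_split(n, pos, n1, pos1, min_samples)
    if (is.null(sp)) return(NULL)
    on1 <- Xi[, sp$feature] == 1L
    list(feature = sp$feature, gain = sp$gain,
         idx1 = idx[on1], idx0 = idx[!on1])
  }
  node_stats <- function(idx) list(n = length(idx), pos = sum(y[idx]))
  root <- grow_node(0L, seq_along(y), max_depth, min_samples, NULL,
                    split_fun, node_stats)
  labels <- if (!is.null(specs)) vapply(specs, feature_label, "") else colnames(X)
  structure(list(root = root, feature_labels = labels, specs = specs,
                 max_depth = max_depth, min_samples = min_samples,
                 n_train = length(y)),
            class = "caax_tree")
}

#' Fit the decision tree over the full CXXX space without materializing X
#'
#' Equivalent to `fit_tree(encode(motifs, enumerate_features(max_set_size)),
#' y)` but computes per-feature contingency counts from per-position residue
#' tallies (a residue-set feature's count is the sum of its members'
#' tallies), so the 8,000 x 65,097 matrix is never built. Feature order, gain
#' criterion and tie-breaks are identical to [fit_tree()].
#'
#' @param labels A `labeled_motifs` object (or list with `motifs`, `label`).
#' @param max_set_size Residue-set size limit (default 5).
#' @param max_depth,min_samples As in [fit_tree()].
#' @return Object of class `caax_tree`.
#' @export
fit_caax_tree <- function(labels, max_set_size = 5L, max_depth = 3L,
                          min_samples = 50L) {
  y <- as.integer(labels$label)
  parts <- motif_parts(labels$motifs)
  codes <- lapply(c("a1", "a2", "x"), function(p) match(parts[[p]], AA_ALPHABET20))
  names(codes) <- c("a1", "a2", "x")
  # membership matrix: sets (size-then-lexicographic order) x 20 residues
  sets <- list()
  for (k in seq_len(max_set_size)) {
    sets <- c(sets, combn(20L, k, simplify = FALSE))
  }
  M <- matrix(0, nrow = length(sets), ncol = 20L)
  for (i in seq_along(sets)) M[i, sets[[i]]] <- 1
  n_sets <- length(sets)

  split_fun <- function(idx) {
    n <- length(idx)
    pos <- sum(y[idx])
    n1 <- numeric(0)
    pos1 <- numeric(0)
    for (p in c("a1", "a2", "x")) {
      cnt <- tabulate(codes[[p]][idx], 20L)
      cntp <- tabulate(codes[[p]][idx][y[idx] == 1L], 20L)
      n1 <- c(n1, as.vector(M %*% cnt))
      pos1 <- c(pos1, as.vector(M %*% cntp))
    }
    sp <- best_split(n, pos, n1, pos1, min_samples)
    if (is.null(sp)) return(NULL)
    p_i <- (sp$feature - 1L) %/% n_sets + 1L
    s_i <- (sp$feature - 1L) %% n_sets + 1L
    pos_lab <- c("a1", "a2", "x")[p_i]
    on1 <- M[s_i, codes[[pos_lab]][idx]] == 1
    list(feature = sp$feature, gain = sp$gain,
         idx1 = idx[on1], idx0 = idx[!on1])
  }
  node_stats <- function(idx) list(n = length(idx), pos = sum(y[idx]))
  root <- grow_node(0L, seq_along(y), max_depth, min_samples, NULL,
                    split_fun, node_stats)
  specs <- list()
  for (pos in c("a1", "a2", "x")) {
    specs <- c(specs, lapply(sets, function(s)
      list(position = pos, residues = AA_ALPHABET20[s])))
  }
  structure(list(root = root, feature_labels = vapply(specs, feature_label, ""),
                 specs = specs, max_depth = max_depth,
                 min_samples = min_samples, n_train = length(y),
                 label_threshold = labels$threshold),
            class = "caax_tree")
}

#' Predict classes for motifs with a fitted tree
#'
#' @param object A `caax_tree` fitted with feature specs (from
#'   [fit_caax_tree()], or [fit_tree()] with `specs`).
#' @param motifs Character vector of motifs.
#' @param ... Unused.
#' @return Character vector "positive"/"negative".
#' @export
predict.caax_tree <- function(object, motifs, ...) {
  if (is.null(object$specs)) {
    stop("tree was fitted without feature specs; cannot evaluate motifs")
  }
  p <- motif_parts(motifs)
  walk <- function(node, sel) {
    if (node$leaf || length(sel) == 0L) {
      return(setNames(rep(node$class, length(sel)), NULL))
    }
    spec <- object$specs[[node$feature]]
    on1 <- p[[spec$position]][sel] %in% spec$residues
    out <- character(length(sel))
    out[on1] <- walk(node$right, sel[on1])
    out[!on1] <- walk(node$left, sel[!on1])
    out
  }
  walk(object$root, seq_along(motifs))
}

#' Predict classes from a matrix-fitted tree
#'
#' Companion to [fit_tree()] when no feature specs are attached: walks the
#' tree using the columns of a feature matrix laid out exactly as the
#' training matrix.
#'
#' @param model A `caax_tree` from [fit_tree()].
#' @param X Binary feature matrix with the training column layout.
#' @return Character vector "positive"/"negative".
#' @export
predict_matrix_tree <- function(model, X) {
  walk <- function(node, sel) {
    if (node$leaf || length(sel) == 0L) {
      return(rep(node$class, length(sel)))
    }
    on1 <- X[sel, node$feature] == 1L
    out <- character(length(sel))
    out[on1] <- walk(node$right, sel[on1])
    out[!on1] <- walk(node$left, sel[!on1])
    out
  }
  walk(model$root, seq_len(nrow(X)))
}

#' @export
print.caax_tree <- function(x, ...) {
  cat("caax_tree (entropy, max_depth =", x$max_depth,
      ", min_samples =", x$min_samples, ", n =", x$n_train, ")\n")
  rec <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, branch, sprintf("leaf: %s (%d pos / %d neg)\n",
                               node$class, node$n_pos, node$n_neg))
    } else {
      cat(pad, branch, sprintf("split on [%s] (gain %.3f, n = %d)\n",
                               x$feature_labels[node$feature], node$gain, node$n))
      rec(node$left, indent + 1L, "no: ")
      rec(node$right, indent + 1L, "yes:")
    }
  }
  rec(x$root, 0L, "")
  invisible(x)
}

#' Extract human-readable rules from a fitted tree
#'
#' One rule per leaf: the conjunction of set-membership conditions along the
#' path, the predicted class, and the leaf purity.
#'
#' @param model A `caax_tree`.
#' @return Character vector of rules (also returned invisibly as a data.frame
#'   attribute `table` with columns rule, class, n, purity).
#' @export
extract_rules <- function(model) {
  rows <- list()
  rec <- function(node, conds) {
    if (node$leaf) {
      purity <- max(node$n_pos, node$n_neg) / max(node$n, 1L)
      rows[[length(rows) + 1L]] <<- data.frame(
        rule = if (length(conds)) paste(conds, collapse = " AND ") else "(always)",
        class = node$class, n = node$n, purity = purity,
        stringsAsFactors = FALSE)
    } else {
      lab <- model$feature_labels[node$feature]
      rec(node$left, c(conds, paste("not", lab)))
      rec(node$right, c(conds, lab))
    }
  }
  rec(model$root, character())
  tab <- do.call(rbind, rows)
  out <- sprintf("IF %s THEN %s  [n = %d, purity = %.1f%%]",
                 tab$rule, tab$class, tab$n, 100 * tab$purity)
  attr(out, "table") <- tab
  out
}

#' Export a fitted tree as JSON
#'
#' @param model A `caax_tree`.
#' @param path Output path.
#' @export
write_tree_json <- function(model, path) {
  strip <- function(node) {
    base <- list(n = node$n, n_pos = node$n_pos, n_neg = node$n_neg,
                 depth = node$depth, class = node$class, leaf = node$leaf)
    if (!node$leaf) {
      base$feature_index <- node$feature
      base$feature <- model$feature_labels[node$feature]
      base$gain <- node$gain
      base$left <- strip(node$left)
      base$right <- strip(node$right)
    }
    base
  }
  jsonlite::write_json(list(max_depth = model$max_depth,
                            min_samples = model$min_samples,
                            n_train = model$n_train,
                            label_threshold = model$label_threshold,
                            tree = strip(model$root)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
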
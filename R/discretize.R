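# Shannon entropy (bits) of a label vector / of class counts
entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

entropy_labels <- function(labels) entropy_counts(table(labels))

#' Supervised MDLP cut points for one numeric feature
#'
#' Recursive entropy minimization with the Fayyad--Irani minimum-description
#' -length stopping criterion. Candidate thresholds are midpoints between
#' adjacent distinct sorted values; a cut is accepted when its information
#' gain exceeds `(log2(N - 1) + log2(3^k - 2) - k*Ent(S) + k1*Ent(S1) +
#' k2*Ent(S2)) / N`, with `k` the number of classes present in the partition
#' being cut. Missing values are ignored.
#'
#' @param values numeric vector.
#' @param labels class labels, same length.
#' @return sorted numeric vector of accepted cut points (possibly empty).
#' @examples
#' mdlp_cuts(c(1, 2, 3, 10, 11, 12), c("N", "N", "N", "Y", "Y", "Y")) # 6.5
#' @export
mdlp_cuts <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  keep <- !is.na(values) & !is.na(labels)
  if (!any(keep)) stop("all values missing")
  values <- values[keep]; labels <- as.character(labels[keep])
  ord <- order(values)
  mdlp_recurse(values[ord], labels[ord])
}

mdlp_recurse <- function(v, y) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  ent_s <- entropy_labels(y)
  if (ent_s == 0) return(numeric(0))

  classes <- unique(y)
  pos <- y == classes[1L]
  # candidate boundaries: last index of each distinct value except the final
  idx <- which(diff(v) > 0)                     # split after position idx
  n_left <- idx
  pos_left <- cumsum(pos)[idx]
  neg_left <- n_left - pos_left
  pos_tot <- sum(pos); neg_tot <- n - pos_tot
  pos_right <- pos_tot - pos_left
  neg_right <- neg_tot - neg_left
  ent2 <- function(a, b) {
    tot <- a + b
    out <- numeric(length(tot))
    nz <- tot > 0
    pa <- ifelse(a[nz] > 0, a[nz] / tot[nz], 1)
    pb <- ifelse(b[nz] > 0, b[nz] / tot[nz], 1)
    out[nz] <- -(a[nz] / tot[nz]) * log2(pa) - (b[nz] / tot[nz]) * log2(pb)
    out
  }
  # binary class assumed for the weighted entropy; general case falls back
  if (length(classes) > 2L) {
    went <- vapply(idx, function(i) {
      (i / n) * entropy_labels(y[seq_len(i)]) +
        ((n - i) / n) * entropy_labels(y[(i + 1L):n])
    }, numeric(1))
  } else {
    went <- (n_left / n) * ent2(pos_left, neg_left) +
      ((n - n_left) / n) * ent2(pos_right, neg_right)
  }
  best <- which.min(went)
  gain <- ent_s - went[best]
  i <- idx[best]
  y1 <- y[seq_len(i)]; y2 <- y[(i + 1L):n]
  k  <- length(classes)
  k1 <- length(unique(y1)); k2 <- length(unique(y2))
  delta <- log2(3^k - 2) - (k * ent_s - k1 * entropy_labels(y1) -
                              k2 * entropy_labels(y2))
  threshold <- (log2(n - 1) + delta) / n
  if (gain <= threshold) return(numeric(0))
  cut <- (v[i] + v[i + 1L]) / 2
  sort(c(mdlp_recurse(v[seq_len(i)], y1), cut,
         mdlp_recurse(v[(i + 1L):n], y2)))
}

#' Build a discretization map for all numeric features of a table
#'
#' Runs [mdlp_cuts()] on every numeric predictor against the class. A
#' feature receiving no cuts carries no information at this resolution and
#' is flagged as dropped for rule mining (it would contribute a single,
#' universal bin).
#'
#' @param table an [item_table()].
#' @param binary_mode if `TRUE`, downstream [apply_discretization()] expands
#'   each bin into its own indicator feature (the binary-discretization mode
#'   used for sparse, imbalanced datasets).
#' @return an object of class `discretization_map`: per-feature sorted cut
#'   points, the dropped-feature set and the mode flag.
#' @export
mdlp_map <- function(table, binary_mode = FALSE) {
  schema <- table$schema
  num_feats <- predictor_names(schema)[
    vapply(predictor_names(schema), function(f) schema$kinds[[f]] == "numeric",
           logical(1))]
  y <- class_vector(table)
  cuts <- lapply(num_feats, function(f) mdlp_cuts(table$data[[f]], y))
  names(cuts) <- num_feats
  dropped <- num_feats[vapply(cuts, length, integer(1)) == 0L]
  structure(list(cuts = cuts, dropped = dropped, binary_mode = binary_mode),
            class = "discretization_map")
}

#' @export
print.discretization_map <- function(x, ...) {
  cat("Discretization map (", if (x$binary_mode) "binary" else "bin-label",
      " mode)\n", sep = "")
  for (nm in names(x$cuts)) {
    if (nm %in% x$dropped) cat("  ", nm, ": no cuts (dropped)\n", sep = "")
    else cat("  ", nm, ": cuts at ", paste(format(x$cuts[[nm]]), collapse = ", "),
             "\n", sep = "")
  }
  invisible(x)
}

bin_labels_for <- function(cuts) {
  edges <- c(-Inf, cuts, Inf)
  vapply(seq_len(length(edges) - 1L), function(i) {
    lo <- edges[i]; hi <- edges[i + 1L]
    if (is.infinite(lo) && is.infinite(hi)) "(-inf-inf)"
    else if (is.infinite(lo)) paste0("(-inf-", format(hi), "]")
    else if (is.infinite(hi)) paste0("(", format(lo), "-inf)")
    else paste0("(", format(lo), "-", format(hi), "]")
  }, character(1))
}

#' Apply a discretization map to a table
#'
#' Each numeric feature is replaced by its bin label (values outside the
#' training range fall into the boundary bins), or in binary mode by one
#' yes/no indicator feature per bin. Dropped features are excluded;
#' categorical features pass through untouched.
#'
#' @param table an [item_table()].
#' @param map a [mdlp_map()] result (must cover all numeric predictors).
#' @return a categorical [item_table()].
#' @export
apply_discretization <- function(table, map) {
  schema <- table$schema
  num_feats <- predictor_names(schema)[
    vapply(predictor_names(schema), function(f) schema$kinds[[f]] == "numeric",
           logical(1))]
  uncovered <- setdiff(num_feats, names(map$cuts))
  if (length(uncovered))
    stop("map does not cover numeric feature(s): ",
         paste(uncovered, collapse = ", "))
  out <- list(); feats <- list()
  for (nm in names(schema$features)) {
    kind <- schema$kinds[[nm]]
    if (nm == schema$class_name || kind == "categorical") {
      out[[nm]] <- table$data[[nm]]
      feats[[nm]] <- schema$features[[nm]]
      next
    }
    if (nm %in% map$dropped) next
    cuts <- map$cuts[[nm]]
    labels <- bin_labels_for(cuts)
    binned <- labels[findInterval(table$data[[nm]], cuts, left.open = TRUE) + 1L]
    binned[is.na(table$data[[nm]])] <- NA
    if (map$binary_mode) {
      for (i in seq_along(labels)) {
        ind_nm <- paste0(nm, "_", i)
        ind <- ifelse(is.na(binned), NA, ifelse(binned == labels[i], "yes", "no"))
        out[[ind_nm]] <- ind
        feats[[ind_nm]] <- c("no", "yes")
      }
    } else {
      out[[nm]] <- binned
      feats[[nm]] <- labels
    }
  }
  new_schema <- feature_schema(feats, schema$class_name, schema$positive_label)
  item_table(as.data.frame(out, check.names = FALSE,
                           stringsAsFactors = FALSE), schema = new_schema)
}

info_gain_feature <- function(col, y) {
  keep <- !is.na(col)
  if (!any(keep)) return(0)
  col <- col[keep]; yk <- y[keep]
  tot <- entropy_labels(yk)
  tab <- table(col, yk)
  n <- sum(tab)
  w <- rowSums(tab) / n
  cond <- sum(w * apply(tab, 1L, entropy_counts))
  tot - cond
}

#' Rank features by information gain and keep the top k
#'
#' Intended for discretized tables; ranks every predictor by its information
#' gain with respect to the class and keeps the `k` best, breaking ties by
#' schema (column) order.
#'
#' @param table an [item_table()] (categorical predictors).
#' @param k number of features to keep, `1 <= k <=` predictor count.
#' @return character vector of the selected feature names, in rank order.
#' @export
rank_and_select <- function(table, k) {
  preds <- predictor_names(table$schema)
  if (k < 1L || k > length(preds)) stop("k must be between 1 and ", length(preds))
  y <- class_vector(table)
  gains <- vapply(preds, function(f) info_gain_feature(table$data[[f]], y),
                  numeric(1))
  ord <- order(-gains, seq_along(preds))   # ties: schema position
  preds[ord][seq_len(k)]
}
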
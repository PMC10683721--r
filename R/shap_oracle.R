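# Brute-force coalition-enumeration Shapley oracle for small tree
# ensembles: the independent verification harness for the fast TreeSHAP
# path. Coalition values are expected margins with absent features
# integrated out by recursive descent over a background table
# (path-dependent weighting by background row counts).

# xgboost stores feature values as float32; replaying tree descent in
# double precision would occasionally flip rows at split boundaries.
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

# Parse a booster's tree dump into plain per-tree lists with integer child
# pointers.
parse_booster_trees <- function(booster) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(booster))
  value_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  lapply(split(dt, dt$Tree), function(tr) {
    id2idx <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    list(feature = tr$Feature,
         split = float32(tr$Split),
         yes = unname(ifelse(is.na(tr$Yes), NA, id2idx[tr$Yes])),
         no = unname(ifelse(is.na(tr$No), NA, id2idx[tr$No])),
         leaf = tr$Feature == "Leaf",
         value = tr[[value_col]])
  })
}

# Background row count reaching every node of one tree.
tree_background_counts <- function(tree, bg) {
  cnt <- numeric(length(tree$feature))
  rec <- function(node, rows) {
    cnt[node] <<- length(rows)
    if (tree$leaf[node]) return(invisible())
    v <- bg[rows, tree$feature[node]]
    go <- v < tree$split[node]
    rec(tree$yes[node], rows[go])
    rec(tree$no[node], rows[!go])
  }
  rec(1L, seq_len(nrow(bg)))
  if (any(cnt == 0)) {
    stop("background table leaves an internal tree node empty")
  }
  cnt
}

# Expected margin of one tree for all rows of `x` under coalition `inS`
# (named logical over features): present features follow their split,
# absent features average the children weighted by background counts.
tree_expected_value <- function(tree, cnt, x, inS) {
  rec <- function(node, rows, out) {
    if (tree$leaf[node]) {
      out[rows] <- tree$value[node]
      return(out)
    }
    f <- tree$feature[node]
    if (isTRUE(inS[[f]])) {
      go <- x[rows, f] < tree$split[node]
      out <- rec(tree$yes[node], rows[go], out)
      rec(tree$no[node], rows[!go], out)
    } else {
      w <- cnt[tree$yes[node]] / cnt[node]
      a <- rec(tree$yes[node], rows, numeric(length(out)))
      b <- rec(tree$no[node], rows, numeric(length(out)))
      out[rows] <- w * a[rows] + (1 - w) * b[rows]
      out
    }
  }
  rec(1L, seq_len(nrow(x)), numeric(nrow(x)))
}

shapley_kernel_weights <- function(m) {
  # w(s) = s! (m - s - 1)! / m!
  vapply(0:(m - 1), function(s) {
    exp(lfactorial(s) + lfactorial(m - s - 1) - lfactorial(m))
  }, 0)
}

interaction_kernel_weights <- function(m) {
  # w(s) = s! (m - s - 2)! / (2 (m - 1)!)
  vapply(0:(m - 2), function(s) {
    exp(lfactorial(s) + lfactorial(m - s - 2) - lfactorial(m - 1)) / 2
  }, 0)
}

#' Exact Shapley values (and pairwise interactions) by coalition enumeration
#'
#' Computes Shapley values as the weighted average of coalition-value
#' differences over all `2^M` feature coalitions, with the coalition value
#' of a row defined as the expected model margin when absent features are
#' integrated out by recursive tree descent over the background table.
#' Pairwise Shapley interaction values use the discrete second difference
#' over coalitions, split half-and-half onto the symmetric entries, with
#' the diagonal holding the main effect (total value minus the off-diagonal
#' row mass) — the same conventions as the fast TreeSHAP path.
#'
#' Intended for fixture-sized models: the cost is exponential in the number
#' of encoded features, and the call refuses more than `max_features`.
#' Matching the fast path exactly additionally requires the booster to have
#' been trained with unit-hessian loss (`reg:squarederror`) on the
#' background table itself, so that xgboost's stored node covers equal
#' background row counts.
#'
#' @param booster An `xgb.Booster` (or a `tv_model`, whose booster is used).
#' @param x Matrix of rows to explain (training schema).
#' @param background Background table (matrix) whose rows define the
#'   integration measure; typically the booster's training data.
#' @param interactions Also compute the pairwise interaction tensor.
#' @param max_features Refuse to enumerate beyond this many features.
#' @return List with `shap` (rows x features), `base` (per-row expected
#'   margin under the empty coalition plus the model's base score) and,
#'   when requested, `interactions` (rows x features x features).
#' @export
exact_shapley_oracle <- function(booster, x, background,
                                 interactions = TRUE, max_features = 10L) {
  if (inherits(booster, "tv_model")) booster <- booster$booster
  feats <- colnames(x)
  m <- length(feats)
  if (m > max_features) {
    stop("refusing coalition enumeration over ", m, " features (limit ",
         max_features, ")")
  }
  stopifnot(identical(colnames(background), feats))
  trees <- parse_booster_trees(booster)
  xf <- apply(x, 2, float32)
  if (nrow(x) == 1) xf <- matrix(xf, 1, dimnames = list(NULL, feats))
  bgf <- apply(background, 2, float32)
  cnts <- lapply(trees, tree_background_counts, bg = bgf)
  n <- nrow(x)

  # v[, S + 1]: expected margin per row for every coalition (bitmask order)
  n_sub <- 2^m
  v <- matrix(0, n, n_sub)
  for (mask in 0:(n_sub - 1)) {
    inS <- stats::setNames(as.logical(bitwAnd(mask, 2^(0:(m - 1)))), feats)
    tot <- numeric(n)
    for (k in seq_along(trees)) {
      tot <- tot + tree_expected_value(trees[[k]], cnts[[k]], xf, inS)
    }
    v[, mask + 1] <- tot
  }
  # align to the booster's margin (absorbs the model's base_score offset)
  full_margin <- stats::predict(booster, x, outputmargin = TRUE)
  offset <- full_margin[1] - v[1, n_sub]
  v <- v + offset

  kw <- shapley_kernel_weights(m)
  shap <- matrix(0, n, m, dimnames = list(NULL, feats))
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    for (sub in 0:(2^(m - 1) - 1)) {
      S <- others[as.logical(bitwAnd(sub, 2^(0:max(0, m - 2))))]
      kS <- sum(2^(S - 1))
      shap[, i] <- shap[, i] +
        kw[length(S) + 1] * (v[, kS + 2^(i - 1) + 1] - v[, kS + 1])
    }
  }
  out <- list(shap = shap, base = v[, 1])

  if (interactions && m >= 2) {
    ikw <- interaction_kernel_weights(m)
    inter <- array(0, c(n, m, m), dimnames = list(NULL, feats, feats))
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        others <- setdiff(seq_len(m), c(i, j))
        acc <- numeric(n)
        for (sub in 0:(2^(m - 2) - 1)) {
          S <- others[as.logical(bitwAnd(sub, 2^(0:max(0, m - 3))))]
          kS <- sum(2^(S - 1))
          d <- v[, kS + 2^(i - 1) + 2^(j - 1) + 1] - v[, kS + 2^(i - 1) + 1] -
            v[, kS + 2^(j - 1) + 1] + v[, kS + 1]
          acc <- acc + ikw[length(S) + 1] * d
        }
        inter[, i, j] <- inter[, j, i] <- acc
      }
    }
    for (i in seq_len(m)) {
      inter[, i, i] <- shap[, i] - rowSums(inter[, i, -i, drop = FALSE], dims = 1)
    }
    out$interactions <- inter
  }
  out
}
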
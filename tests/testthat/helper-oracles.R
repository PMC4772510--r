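# Independent oracles and small fixture builders shared across the suite.

# Brute-force GINI split search: enumerates every (feature, midpoint) pair
# with the same tie rule as the implementation (lowest feature, then lowest
# threshold, strict improvement). Kept deliberately naive.
oracle_best_split <- function(X, y, min_gain = 1e-7) {
  n <- nrow(X)
  n1 <- sum(y == 1L); n0 <- n - n1
  parent <- 1 - (n0^2 + n1^2) / n^2
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (k in seq_len(length(v) - 1)) {
      thr <- (v[k] + v[k + 1]) / 2
      left <- X[, j] <= thr
      nl <- sum(left); nr <- n - nl
      if (nl == 0 || nr == 0) next
      l1 <- sum(y[left] == 1L); l0 <- nl - l1
      r1 <- n1 - l1; r0 <- nr - r1
      gl <- 1 - (l0^2 + l1^2) / nl^2
      gr <- 1 - (r0^2 + r1^2) / nr^2
      gain <- parent - (nl * gl + nr * gr) / n
      if (is.null(best) || gain > best$gain + 1e-15) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  if (is.null(best) || best$gain <= min_gain) NULL else best
}

# Pairwise Mann-Whitney AUC, ties counted 1/2 -- quadratic, oracle only.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Held-out accuracy of scikit-learn's RandomForestClassifier on feature CSVs
# written by write_feature_table(); the independent reference forest.
sklearn_rf_accuracy <- function(train_csv, test_csv, n_trees, max_features,
                                seed) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import pandas as pd",
    "from sklearn.ensemble import RandomForestClassifier",
    "tr = pd.read_csv(sys.argv[1]); te = pd.read_csv(sys.argv[2])",
    "Xtr = tr.drop(columns=['id', 'activity']); ytr = tr['activity']",
    "Xte = te.drop(columns=['id', 'activity']); yte = te['activity']",
    "m = RandomForestClassifier(n_estimators=int(sys.argv[3]),",
    "    max_features=int(sys.argv[4]), random_state=int(sys.argv[5]))",
    "m.fit(Xtr, ytr)",
    "print('%.10f' % m.score(Xte, yte))"
  ), script)
  out <- system2("python", c(script, train_csv, test_csv, n_trees,
                             max_features, seed), stdout = TRUE)
  as.numeric(out[length(out)])
}

# labelled feature table from a plain matrix + 0/1 labels
make_table <- function(X, y = NULL) {
  feature_table(as.matrix(X), labels = y)
}

# train/test split of a feature table, deterministic in seed
split_table <- function(table, test_fraction, seed) {
  n <- nrow(table$matrix)
  set.seed(seed)
  te <- sample.int(n, round(n * test_fraction))
  tr <- setdiff(seq_len(n), te)
  list(train = rfscreen:::ft_rows(table, tr),
       test = rfscreen:::ft_rows(table, te))
}
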
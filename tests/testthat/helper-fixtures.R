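# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (loops, direct definitions) and independent of the
# package implementation they check.

options(cpscreen.log_level = "error")

# small random single-cell table
random_cell_table <- function(n_cells = 30, n_features = 4, seed = 1) {
  set.seed(seed)
  wells <- sample(c("A02", "B05", "C10"), n_cells, replace = TRUE)
  m <- matrix(rnorm(n_cells * n_features), n_cells)
  colnames(m) <- paste0("feat", seq_len(n_features))
  single_cell_table(wells, m)
}

# a minimal valid 384-well plate map data.frame
full_plate_df <- function(n_ref = 4, condition = "resting") {
  wells <- all_wells()
  df <- data.frame(well = wells, role = "experimental",
                   compound_id = paste0("c", seq_along(wells)),
                   dose_uM = 10, condition = condition,
                   stringsAsFactors = FALSE)
  df$role[1] <- "dye_control"; df$compound_id[1] <- NA
  df$role[384] <- "dye_control"; df$compound_id[384] <- NA
  ref <- 1 + seq_len(n_ref)
  df$role[ref] <- "reference_control"
  df$compound_id[ref] <- NA
  df
}

# brute-force oracles -----------------------------------------------------

oracle_cp_score <- function(x) {
  x <- x[!is.na(x)]
  s <- 0
  for (v in x) s <- s + v^2
  s / length(x)
}

oracle_iqr_threshold <- function(scores) {
  q3 <- quantile(scores, 0.75, type = 7, names = FALSE)
  max(scores[scores <= q3])
}

oracle_fdr_threshold <- function(scores, q = 0.05) {
  n_excl <- ceiling(q * length(scores))
  if (n_excl >= length(scores)) n_excl <- length(scores) - 1
  sorted <- sort(scores, decreasing = TRUE)
  sorted[n_excl + 1]
}

oracle_elbow_threshold <- function(scores) {
  y <- sort(scores)
  n <- length(y)
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- abs(xs[i] - ys[i]) / sqrt(2)
  y[which.max(d)]
}

oracle_pearson_similarity <- function(m) {
  n <- nrow(m)
  s <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s[i, j] <- cor(m[i, ], m[j, ])
  }
  s
}

# naive complete-linkage merge heights on a distance matrix
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# planted consolidation scenario: 4 tight background clusters; the class's
# 6 members sit in different clusters at rest and collapse into one under
# activation
planted_consolidation_data <- function(seed, k = 4, members = 6) {
  set.seed(seed)
  centers <- matrix(rnorm(k * 8, sd = 6), k, 8)
  bg <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rep(centers[j, ], each = 8), 8) + rnorm(64, sd = 0.3)
  }))
  mem_r <- t(sapply(seq_len(members), function(i) {
    centers[(i - 1) %% k + 1, ] + rnorm(8, sd = 0.3)
  }))
  mem_a <- t(sapply(seq_len(members), function(i) {
    centers[1, ] + rnorm(8, sd = 0.3)
  }))
  resting <- rbind(mem_r, bg)
  activated <- rbind(mem_a, bg)
  ids <- paste0("c", seq_len(nrow(resting)))
  rownames(resting) <- rownames(activated) <- ids
  list(resting = resting, activated = activated,
       classes = data.frame(compound_id = ids[seq_len(members)],
                            class = "planted", stringsAsFactors = FALSE))
}

oracle_shannon_entropy <- function(labels) {
  tab <- table(labels)
  h <- 0
  for (k in tab) {
    p <- k / length(labels)
    h <- h - p * log2(p)
  }
  h
}
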
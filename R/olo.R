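# Exact optimal leaf ordering for a dendrogram (dynamic programming over
# (leftmost, rightmost) leaf pairs): among the 2^(n-1) orderings consistent
# with the tree, finds one minimizing the sum of distances between adjacent
# leaves.

olo_order <- function(hc, D) {
  n <- nrow(D)
  if (n == 1) return(1L)
  D <- as.matrix(D)
  merge <- hc$merge
  leaves <- vector("list", n - 1)
  M <- vector("list", n - 1)

  child_info <- function(id) {
    if (id < 0) {
      l <- -id
      list(leaves = l, M = matrix(0, 1, 1, dimnames = list(l, l)))
    } else {
      list(leaves = leaves[[id]], M = M[[id]])
    }
  }

  for (k in seq_len(n - 1)) {
    L <- child_info(merge[k, 1])
    R <- child_info(merge[k, 2])
    ML <- L$M; MR <- R$M
    Dl <- D[L$leaves, R$leaves, drop = FALSE]
    # Tm[u, m2] = min_{m1 in L} ML[u, m1] + D[m1, m2]
    Tm <- matrix(Inf, length(L$leaves), length(R$leaves))
    for (j in seq_along(R$leaves)) {
      Tm[, j] <- apply(ML + rep(Dl[, j], each = nrow(ML)), 1, min)
    }
    # cost[u, w] = min_{m2 in R} Tm[u, m2] + MR[m2, w]
    cost <- matrix(Inf, length(L$leaves), length(R$leaves),
                   dimnames = list(L$leaves, R$leaves))
    for (j in seq_along(R$leaves)) {
      cost[, j] <- apply(Tm + rep(MR[, j], each = nrow(Tm)), 1, min)
    }
    lv <- c(L$leaves, R$leaves)
    full <- matrix(Inf, length(lv), length(lv), dimnames = list(lv, lv))
    full[as.character(L$leaves), as.character(R$leaves)] <- cost
    full[as.character(R$leaves), as.character(L$leaves)] <- t(cost)
    leaves[[k]] <- lv
    M[[k]] <- full
  }

  rec <- function(id, u, w) {
    if (id < 0) return(-id)
    left_id <- merge[id, 1]; right_id <- merge[id, 2]
    L <- child_info(left_id); R <- child_info(right_id)
    if (!(u %in% L$leaves)) {
      tmp <- L; L <- R; R <- tmp
      tmp_id <- left_id; left_id <- right_id; right_id <- tmp_id
    }
    best <- Inf; bm1 <- NA; bm2 <- NA
    for (m1 in L$leaves) for (m2 in R$leaves) {
      v <- L$M[as.character(u), as.character(m1)] + D[m1, m2] +
        R$M[as.character(m2), as.character(w)]
      if (v < best) { best <- v; bm1 <- m1; bm2 <- m2 }
    }
    c(rec(left_id, u, bm1), rec(right_id, bm2, w))
  }

  root <- n - 1
  Mr <- M[[root]]
  pos <- which(Mr == min(Mr), arr.ind = TRUE)[1, ]
  u <- as.integer(rownames(Mr)[pos[1]])
  w <- as.integer(colnames(Mr)[pos[2]])
  as.integer(rec(root, u, w))
}

# total distance between adjacent leaves for a given order
adjacent_distance_sum <- function(D, ord) {
  D <- as.matrix(D)
  sum(D[cbind(ord[-length(ord)], ord[-1])])
}
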
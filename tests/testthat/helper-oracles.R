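# Independent brute-force oracles. Everything here is written as direct
# enumeration with explicit loops, deliberately sharing no code with the
# package's vectorized implementations.

oracle_dirs13 <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ])
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    v <- d[i, ]
    nz <- v[v != 0]
    keep[i] <- nz[length(nz)] > 0
  }
  d[keep, , drop = FALSE]
}

oracle_dirs26 <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ])
}

in_bounds <- function(p, dm) all(p >= 1) && all(p <= dm)

## GLCM: count all symmetric co-occurring level pairs at the given distance.
oracle_glcm <- function(lv, ng, distance = 1L) {
  dm <- dim(lv)
  dirs <- oracle_dirs13() * distance
  acc <- matrix(0, ng, ng)
  for (k in seq_len(nrow(dirs))) {
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      q <- c(x, y, z) + dirs[k, ]
      if (!in_bounds(q, dm)) next
      a <- lv[x, y, z]; b <- lv[q[1], q[2], q[3]]
      if (is.na(a) || is.na(b)) next
      acc[a, b] <- acc[a, b] + 1
      acc[b, a] <- acc[b, a] + 1
    }
  }
  if (sum(acc) == 0) { acc[1, 1] <- 1 }
  acc / sum(acc)
}

## GLRLM: enumerate maximal runs; a voxel starts a run if its predecessor
## along the direction is out of bounds, masked out, or a different level.
oracle_glrlm <- function(lv, ng) {
  dm <- dim(lv)
  dirs <- oracle_dirs13()
  max_len <- sum(dm)
  acc <- matrix(0, ng, max_len)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      v <- lv[x, y, z]
      if (is.na(v)) next
      p_prev <- c(x, y, z) - d
      if (in_bounds(p_prev, dm)) {
        pv <- lv[p_prev[1], p_prev[2], p_prev[3]]
        if (!is.na(pv) && pv == v) next  # not a run start
      }
      len <- 1L
      p <- c(x, y, z) + d
      while (in_bounds(p, dm)) {
        nv <- lv[p[1], p[2], p[3]]
        if (is.na(nv) || nv != v) break
        len <- len + 1L
        p <- p + d
      }
      acc[v, len] <- acc[v, len] + 1
    }
  }
  acc <- acc / nrow(dirs)
  acc[, 1:max(which(colSums(acc) > 0)), drop = FALSE]
}

## GLSZM: flood-fill 26-connected equal-level zones with an explicit stack.
oracle_glszm <- function(lv, ng) {
  dm <- dim(lv)
  seen <- array(FALSE, dm)
  dirs <- oracle_dirs26()
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (is.na(lv[x, y, z]) || seen[x, y, z]) next
    level <- lv[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (k in seq_len(nrow(dirs))) {
        q <- p + dirs[k, ]
        if (!in_bounds(q, dm)) next
        if (seen[q[1], q[2], q[3]]) next
        qv <- lv[q[1], q[2], q[3]]
        if (is.na(qv) || qv != level) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- c(level, size)
  }
  max_size <- max(vapply(zones, `[`, integer(1), 2L))
  acc <- matrix(0, ng, max_size)
  for (zn in zones) acc[zn[1], zn[2]] <- acc[zn[1], zn[2]] + 1
  acc
}

## GLDM: count dependent neighbors voxel by voxel; size = count + 1.
oracle_gldm <- function(lv, ng, alpha = 0) {
  dm <- dim(lv)
  dirs <- oracle_dirs26()
  sizes <- integer(0); levels <- integer(0)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- lv[x, y, z]
    if (is.na(v)) next
    cnt <- 0L
    for (k in seq_len(nrow(dirs))) {
      q <- c(x, y, z) + dirs[k, ]
      if (!in_bounds(q, dm)) next
      qv <- lv[q[1], q[2], q[3]]
      if (!is.na(qv) && abs(qv - v) <= alpha) cnt <- cnt + 1L
    }
    sizes <- c(sizes, cnt + 1L); levels <- c(levels, v)
  }
  acc <- matrix(0, ng, max(sizes))
  for (i in seq_along(sizes))
    acc[levels[i], sizes[i]] <- acc[levels[i], sizes[i]] + 1
  acc
}

## NGTDM: per-level counts and summed deviations from the neighborhood mean.
oracle_ngtdm <- function(lv, ng) {
  dm <- dim(lv)
  dirs <- oracle_dirs26()
  n_i <- integer(ng); s_i <- numeric(ng)
  total <- 0L
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- lv[x, y, z]
    if (is.na(v)) next
    nb <- numeric(0)
    for (k in seq_len(nrow(dirs))) {
      q <- c(x, y, z) + dirs[k, ]
      if (!in_bounds(q, dm)) next
      qv <- lv[q[1], q[2], q[3]]
      if (!is.na(qv)) nb <- c(nb, qv)
    }
    if (!length(nb)) next
    n_i[v] <- n_i[v] + 1L
    s_i[v] <- s_i[v] + abs(v - mean(nb))
    total <- total + 1L
  }
  data.frame(level = 1:ng, n = n_i, p = n_i / total, s = s_i)
}

## random small discretized ROI (with ragged mask) for oracle comparisons
random_droi <- function(seed, max_dim = c(5, 5, 3), n_levels = 4) {
  set.seed(seed)
  dm <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
          sample(1:max_dim[3], 1))
  lv <- array(sample.int(n_levels, prod(dm), replace = TRUE), dm)
  mask <- array(runif(prod(dm)) < 0.85, dm)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  lv[!mask] <- NA_integer_
  structure(list(levels = lv, intensities = lv[mask], mask = mask,
                 spacing = c(1, 1, 1), ng = n_levels, n_bins = n_levels,
                 degenerate = FALSE), class = "droi")
}

## ---- graph topology oracle -------------------------------------------------

## Direct formulae + Floyd-Warshall, from an adjacency matrix over the nodes
## that carry at least one edge.
oracle_topology <- function(adj) {
  deg_all <- rowSums(adj)
  keep <- deg_all > 0
  if (!any(keep))
    return(list(diameter = 0, n_edges = 0, n_nodes = 0, centralization = 0,
                heterogeneity = 0, density = 0, clustering = 0,
                char_path_length = 0, mean_degree = 0))
  a <- adj[keep, keep, drop = FALSE]
  n <- nrow(a)
  deg <- rowSums(a)
  m <- sum(a) / 2
  density <- 2 * m / (n * (n - 1))
  ## local clustering over nodes with degree >= 2
  cc <- c()
  for (i in 1:n) {
    if (deg[i] < 2) next
    nb <- which(a[i, ] == 1)
    links <- sum(a[nb, nb]) / 2
    cc <- c(cc, links / choose(length(nb), 2))
  }
  clustering <- if (length(cc)) mean(cc) else 0
  ## components by BFS
  comp <- rep(0L, n); cid <- 0L
  for (s in 1:n) {
    if (comp[s] != 0) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(a[u, ] == 1)) if (comp[v] == 0) {
        comp[v] <- cid; queue <- c(queue, v)
      }
    }
  }
  ## largest component; ties: most edges, then smallest member index
  ## (node names here are LETTERS, so index order = name order)
  sizes <- tabulate(comp)
  edges_in <- vapply(seq_len(cid), function(ci) {
    mem <- which(comp == ci)
    sum(a[mem, mem]) / 2
  }, numeric(1))
  cand2 <- which(sizes == max(sizes))
  cand2 <- cand2[edges_in[cand2] == max(edges_in[cand2])]
  if (length(cand2) > 1) {
    firsts <- vapply(cand2, function(ci) min(which(comp == ci)), numeric(1))
    cand2 <- cand2[which.min(firsts)]
  }
  nodes <- which(comp == cand2[1])
  d <- matrix(Inf, length(nodes), length(nodes))
  diag(d) <- 0
  for (i in seq_along(nodes)) for (j in seq_along(nodes))
    if (a[nodes[i], nodes[j]] == 1) d[i, j] <- 1
  for (k in seq_along(nodes)) for (i in seq_along(nodes))
    for (j in seq_along(nodes))
      if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  off <- d[upper.tri(d)]
  diameter <- if (length(off)) max(off) else 0
  cpl <- if (length(off)) mean(off) else 0
  centralization <- if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density)
                    else 0
  heterogeneity <- sqrt(mean((deg - mean(deg))^2)) / mean(deg)
  list(diameter = diameter, n_edges = m, n_nodes = n,
       centralization = centralization, heterogeneity = heterogeneity,
       density = density, clustering = clustering, char_path_length = cpl,
       mean_degree = 2 * m / n)
}

## adjacency matrix -> cell_network-shaped list
adj_to_net <- function(adj, names_ = LETTERS[seq_len(nrow(adj))]) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  list(nodes = names_,
       edges = data.frame(source = names_[idx[, 1]],
                          target = names_[idx[, 2]],
                          weight = rep(1, nrow(idx))),
       r_threshold = 0.5)
}

## ---- AUC / Wilcoxon / log-rank oracles -------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## exact signed-rank p by enumerating all sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    vs[m + 1] <- sum(rk[signs])
  }
  mu <- n * (n + 1) / 4
  p_ge <- mean(vs >= v_obs); p_le <- mean(vs <= v_obs)
  min(1, 2 * if (v_obs > mu) p_ge else p_le)
}

## hand-built expected/observed log-rank chi-square
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d_t * n1 / n_t
    if (n_t > 1)
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chisq <- (o1 - e1)^2 / v
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}
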
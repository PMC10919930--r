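# Internal scan engine.
#
# Per alignment column we test the allele factor with a partial F test:
# response = log body mass over species with a non-missing allele, reduced
# model = intercept (optionally + habitat), full model = reduced + allele
# factor. Because the design of every column depends only on the alignment
# and the habitat labels — never on the (permuted) masses — we precompute,
# once per alignment, an orthonormal basis Qr of each column's reduced model
# space and a basis Qa of the allele factor's orthogonal complement within
# the full model. For any response vector y (real or permuted):
#
#   SS_allele = ||Qa' y||^2,  RSS = ||y_used||^2 - ||Qr' y||^2 - ||Qa' y||^2,
#   F = (SS_allele / df_a) / (RSS / df_e).
#
# Stacking all columns' bases into two wide matrices turns a whole-alignment
# scan into a handful of BLAS calls, which is what makes 2 x 1,000
# permutation runs on tens of thousands of columns tractable.

prepare_scan <- function(aln, traits, model = c("allele", "allele_habitat")) {
  model <- match.arg(model)
  sp <- rownames(aln)
  if (is.null(sp) || ncol(aln) < 1) abort("Alignment is empty or unnamed.")
  missing_sp <- setdiff(sp, traits$species)
  if (length(missing_sp) > 0) {
    abort(paste("Species missing from trait table:",
                paste(missing_sp, collapse = ", ")))
  }
  tt <- traits[match(sp, traits$species), ]
  n <- length(sp)
  p <- ncol(aln)
  habitat <- tt$habitat

  used_m <- matrix(aln %in% BASES, n, p)
  df_a <- df_e <- n_used <- n_classes <- integer(p)
  tested <- logical(p)
  flags <- vector("list", p)
  Qr_list <- Qa_list <- vector("list", p)

  for (j in seq_len(p)) {
    used <- used_m[, j]
    nu <- sum(used)
    n_used[j] <- nu
    fl <- character(0)
    al <- aln[used, j]
    k <- length(unique(al))
    n_classes[j] <- k
    if (k >= 2 && any(tabulate(factor(al)) == 1)) fl <- c(fl, "singleton_class")
    if (k < 2) {
      flags[[j]] <- c(fl, "monomorphic_skipped")
      next
    }
    if (nu < 3) {
      flags[[j]] <- c(fl, "insufficient_df_skipped")
      next
    }
    Xr <- matrix(1, nu, 1)
    if (model == "allele_habitat") {
      Xr <- cbind(Xr, as.numeric(habitat[used] == "aquatic"))
    }
    qr_r <- qr(Xr)
    rr <- qr_r$rank
    Qru <- qr.Q(qr_r)[, seq_len(rr), drop = FALSE]
    Z <- outer(al, unique(al), "==") * 1
    Za <- Z - Qru %*% crossprod(Qru, Z)
    # absolute tolerance: Z is a 0/1 design, so any genuinely new direction
    # has norm well above 1e-8; qr()'s relative rank would miscount an
    # all-roundoff Za (allele collinear with the covariate) as full rank
    qr_a <- qr(Za)
    dR <- abs(diag(qr_a$qr))
    da <- sum(dR[seq_len(min(dim(Za)))] > 1e-8)
    if (da < 1) {
      flags[[j]] <- c(fl, "collinear_skipped")
      next
    }
    de <- nu - rr - da
    if (de < 1) {
      flags[[j]] <- c(fl, "insufficient_df_skipped")
      next
    }
    Qau <- qr.Q(qr_a)[, seq_len(da), drop = FALSE]
    Qr <- matrix(0, n, rr)
    Qr[used, ] <- Qru
    Qa <- matrix(0, n, da)
    Qa[used, ] <- Qau
    Qr_list[[j]] <- Qr
    Qa_list[[j]] <- Qa
    df_a[j] <- da
    df_e[j] <- de
    tested[j] <- TRUE
    flags[[j]] <- fl
  }

  tcols <- which(tested)
  pt <- length(tcols)
  if (pt > 0) {
    Qr_big <- do.call(cbind, Qr_list[tcols])
    Qa_big <- do.call(cbind, Qa_list[tcols])
    gr_idx <- rep(seq_len(pt), vapply(Qr_list[tcols], ncol, integer(1)))
    ga_idx <- rep(seq_len(pt), vapply(Qa_list[tcols], ncol, integer(1)))
    M <- used_m[, tcols, drop = FALSE] * 1
  } else {
    Qr_big <- Qa_big <- matrix(0, n, 0)
    gr_idx <- ga_idx <- integer(0)
    M <- matrix(0, n, 0)
  }

  list(model = model, species = sp, habitat = habitat, n = n, p = p,
       tested = tested, tested_cols = tcols, p_tested = pt,
       n_used = n_used, n_classes = n_classes, flags = flags,
       df_a = df_a[tcols], df_e = df_e[tcols],
       Qr_big = Qr_big, Qa_big = Qa_big,
       gr_idx = gr_idx, ga_idx = ga_idx, M = M)
}

# F statistics for a batch of response vectors. Y: n x B matrix (rows in
# prep$species order). Returns list of p_tested x B matrices.
engine_stats <- function(prep, Y) {
  Y <- as.matrix(Y)
  y2 <- crossprod(prep$M, Y^2)
  SSr <- rowsum(crossprod(prep$Qr_big, Y)^2, prep$gr_idx)
  SSa <- rowsum(crossprod(prep$Qa_big, Y)^2, prep$ga_idx)
  RSS <- pmax(y2 - SSr - SSa, 0)
  zero_res <- RSS <= 1e-12 * pmax(y2, .Machine$double.eps)
  Fm <- (SSa / prep$df_a) / (RSS / prep$df_e)
  Fm[zero_res] <- Inf
  list(F = Fm, RSS = RSS, SSa = SSa, zero_res = zero_res)
}

# p-values for a single response vector.
engine_pvalues <- function(prep, y) {
  st <- engine_stats(prep, matrix(y, ncol = 1))
  Fv <- st$F[, 1]
  pv <- pf(Fv, prep$df_a, prep$df_e, lower.tail = FALSE)
  pv[st$zero_res[, 1]] <- 0
  list(F = Fv, p = pv, zero_res = st$zero_res[, 1])
}

# Hit counts per batch column at each threshold, via per-column critical F
# values (p <= t  <=>  F >= qf(1 - t, df_a, df_e)).
engine_hits <- function(prep, Y, fcrit_list) {
  st <- engine_stats(prep, Y)
  hits <- vapply(fcrit_list, function(fc) colSums(st$F >= fc),
                 numeric(ncol(st$F)))
  matrix(hits, nrow = ncol(st$F), ncol = length(fcrit_list))
}

critical_f <- function(prep, thresholds) {
  lapply(thresholds, function(t) qf(1 - t, prep$df_a, prep$df_e))
}

# Column of permuted responses: masses shuffled across all species, or within
# habitat strata.
perm_response_matrix <- function(y, habitat, B, stratified) {
  n <- length(y)
  Y <- matrix(0, n, B)
  if (!stratified) {
    for (b in seq_len(B)) Y[, b] <- y[sample.int(n)]
  } else {
    groups <- split(seq_len(n), habitat)
    for (b in seq_len(B)) {
      idx <- integer(n)
      for (g in groups) idx[g] <- g[sample.int(length(g))]
      Y[, b] <- y[idx]
    }
  }
  Y
}
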
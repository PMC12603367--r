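# Reverse-mode gradients through the full model.  Mirrors
# pst_forward_core step by step using the cache it produced; validated
# against central finite differences in the test suite.  Gradient lists
# share the exact shape and names of the parameter lists so the flat
# optimizer in params.R can walk both in lockstep.

zero_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
}

# d(loss)/d(logits) for the masked-LM objective (mean over masked rows).
mlm_loss_grad <- function(logits, mask_rows, targets) {
  d <- matrix(0, nrow(logits), ncol(logits))
  nm <- length(mask_rows)
  for (k in seq_len(nm)) {
    r <- mask_rows[k]
    p <- exp(log_softmax_vec(logits[r, ]))
    p[targets[k]] <- p[targets[k]] - 1
    d[r, ] <- p / nm
  }
  d
}

pst_backward <- function(cache, dlogits, config, backbone, adapter, adapter_cfg) {
  Tn <- length(cache$ids)
  d <- config$model_dim
  h <- config$n_heads; dh <- d %/% h
  use_struct <- cache$use_struct
  res <- cache$res

  gb <- list(emb = zero_like(backbone$emb),
             layers = vector("list", config$n_layers),
             lnf_g = NULL, lnf_b = NULL, lm_w = NULL, lm_b = NULL)
  ga <- if (use_struct) vector("list", config$n_layers) else NULL

  # LM head + final norm
  gb$lm_w <- t(cache$Yf) %*% dlogits
  gb$lm_b <- colSums(dlogits)
  dYf <- dlogits %*% t(backbone$lm_w)
  lb <- ln_bwd(dYf, cache$lnf, backbone$lnf_g)
  gb$lnf_g <- lb$dg; gb$lnf_b <- lb$db
  dX <- lb$dx

  for (l in rev(seq_len(config$n_layers))) {
    lp <- backbone$layers[[l]]
    cc <- cache$layers[[l]]
    gl <- list()

    # FFN branch: X2 = X1 + act(B w1 + b1) w2 + b2, B = LN2(X1)
    dF <- dX
    gl$b2 <- colSums(dF)
    gl$w2 <- t(cc$Hact) %*% dF
    dHact <- dF %*% t(lp$w2)
    dpre <- act_bwd(dHact, cc$pre, config$activation)
    gl$w1 <- t(cc$B) %*% dpre
    gl$b1 <- colSums(dpre)
    dB <- dpre %*% t(lp$w1)
    l2 <- ln_bwd(dB, cc$ln2, lp$ln2_g)
    gl$ln2_g <- l2$dg; gl$ln2_b <- l2$db
    dX1 <- dX + l2$dx

    # attention branch: X1 = X_in + concat %*% wo + bo
    ac <- cc$attn
    dAP <- dX1
    gl$bo <- colSums(dAP)
    gl$wo <- t(ac$concat) %*% dAP
    dconcat <- dAP %*% t(lp$wo)
    dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
    for (hh in seq_len(h)) {
      idx <- ((hh - 1L) * dh + 1L):(hh * dh)
      hd <- ac$heads[[hh]]
      dO <- dconcat[, idx, drop = FALSE]
      dP <- dO %*% t(ac$V[, idx, drop = FALSE])
      dV[, idx] <- t(hd$P) %*% dO
      dS <- hd$P * (dP - rowSums(dP * hd$P))
      dS <- dS / sqrt(dh)
      dQr <- dS %*% hd$Kr
      dKr <- t(dS) %*% hd$Qr
      dQ[, idx] <- rotary_transform(dQr, ac$positions, config$rotary_base, inverse = TRUE)
      dK[, idx] <- rotary_transform(dKr, ac$positions, config$rotary_base, inverse = TRUE)
    }
    A <- cc$A
    gl$wq <- t(A) %*% dQ; gl$bq <- colSums(dQ)
    gl$wk <- t(A) %*% dK; gl$bk <- colSums(dK)
    gl$wv <- t(A) %*% dV; gl$bv <- colSums(dV)
    dA <- dQ %*% t(lp$wq) + dK %*% t(lp$wk) + dV %*% t(lp$wv)

    if (use_struct) {
      al <- adapter[[l]]
      S <- ac$S
      gal <- list(gin = NULL,
                  wqs = t(S) %*% dQ, wks = t(S) %*% dK, wvs = t(S) %*% dV)
      dS_full <- dQ %*% t(al$wqs) + dK %*% t(al$wks) + dV %*% t(al$wvs)
      gbk <- gin_bwd(dS_full[res, , drop = FALSE], cc$gin, al$gin, adapter_cfg)
      gal$gin <- gbk$grads
      dA[res, ] <- dA[res, , drop = FALSE] + gbk$dH
      ga[[l]] <- gal
    }

    l1 <- ln_bwd(dA, cc$ln1, lp$ln1_g)
    gl$ln1_g <- l1$dg; gl$ln1_b <- l1$db
    dX <- dX1 + l1$dx

    # order gradients like the parameter list for name-aligned flattening
    gb$layers[[l]] <- gl[c("ln1_g", "ln1_b", "wq", "bq", "wk", "bk", "wv", "bv",
                           "wo", "bo", "ln2_g", "ln2_b", "w1", "b1", "w2", "b2")]
  }

  # embedding rows
  rs <- rowsum(dX, group = cache$ids)
  gb$emb[as.integer(rownames(rs)), ] <- rs

  list(backbone = gb, adapter = ga)
}
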
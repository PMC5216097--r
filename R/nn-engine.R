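# Internal mini network engine.
#
# Activations travel as D x N matrices (one column per sample). Spatial
# blobs are flattened in (H fastest, then W, then channel) order. Convolution
# and pooling are realized as precomputed index gathers (im2col) followed by
# BLAS matrix products, which keeps the whole forward/backward pass inside
# vectorized primitives. Shape arithmetic: conv uses floor, pooling uses
# ceiling with the overhang padded by -Inf (so clipped windows ignore the
# padding). These are the only conventions consistent with the reference
# blob-shape table for both the 64-px and 56-px inputs.

conv_out_side <- function(side, k, s, p) floor((side + 2 * p - k) / s) + 1
pool_out_side <- function(side, k, s) ceiling((side - k) / s) + 1

# Build the gather-index machinery for one conv layer.
compile_conv <- function(h, w, cin, z, s, p, cout) {
  hp <- h + 2 * p; wp <- w + 2 * p
  hout <- conv_out_side(h, z, s, p); wout <- conv_out_side(w, z, s, p)
  if (hout < 1 || wout < 1) stop("conv output side non-positive", call. = FALSE)
  kh <- rep(0:(z - 1), times = z * cin)
  kw <- rep(rep(0:(z - 1), each = z), times = cin)
  kc <- rep(0:(cin - 1), each = z * z)
  rowpart <- kh + hp * kw + hp * wp * kc
  oh <- rep(0:(hout - 1), times = wout)
  ow <- rep(0:(wout - 1), each = hout)
  colpart <- oh * s + hp * (ow * s)
  idx <- outer(rowpart, colpart, `+`) + 1L
  storage.mode(idx) <- "integer"
  # map original (unpadded) rows into the padded buffer
  origpos <- if (p > 0) {
    hh <- rep(0:(h - 1), times = w * cin)
    ww <- rep(rep(0:(w - 1), each = h), times = cin)
    cc <- rep(0:(cin - 1), each = h * w)
    (hh + p) + hp * (ww + p) + hp * wp * cc + 1L
  } else NULL
  list(kind = "conv", z = z, s = s, p = p, cin = cin, cout = cout,
       h = h, w = w, hp = hp, wp = wp, hout = hout, wout = wout,
       K = z * z * cin, P = hout * wout, idx = idx,
       origpos = origpos, dpad = hp * wp * cin,
       out_dim = hout * wout * cout,
       out_shape = c(hout, wout, cout))
}

compile_pool <- function(h, w, cin, z, s) {
  hout <- pool_out_side(h, z, s); wout <- pool_out_side(w, z, s)
  hp <- max(h, (hout - 1) * s + z); wp <- max(w, (wout - 1) * s + z)
  kh <- rep(0:(z - 1), times = z)
  kw <- rep(0:(z - 1), each = z)
  rowpart <- kh + hp * kw
  oh <- rep(0:(hout - 1), times = wout * cin)
  ow <- rep(rep(0:(wout - 1), each = hout), times = cin)
  oc <- rep(0:(cin - 1), each = hout * wout)
  colpart <- oh * s + hp * (ow * s) + hp * wp * oc
  idx <- outer(rowpart, colpart, `+`) + 1L
  storage.mode(idx) <- "integer"
  origpos <- if (hp > h || wp > w) {
    hh <- rep(0:(h - 1), times = w * cin)
    ww <- rep(rep(0:(w - 1), each = h), times = cin)
    cc <- rep(0:(cin - 1), each = h * w)
    hh + hp * ww + hp * wp * cc + 1L
  } else NULL
  list(kind = "maxpool", z = z, s = s, cin = cin,
       h = h, w = w, hp = hp, wp = wp, hout = hout, wout = wout,
       z2 = z * z, Q = hout * wout * cin, idx = idx,
       origpos = origpos, dpad = hp * wp * cin,
       out_dim = hout * wout * cin,
       out_shape = c(hout, wout, cin))
}

# Compile a declarative spec into per-layer execution descriptors.
compile_net <- function(spec) {
  shp <- spec$input_shape            # (channels, side, side)
  h <- shp[2]; w <- shp[3]; cin <- shp[1]
  spatial <- TRUE
  layers <- list()
  for (ls in spec$layers) {
    lay <- switch(ls$kind,
      conv = {
        if (!spatial) stop("conv after flatten", call. = FALSE)
        l <- compile_conv(h, w, cin, ls$kernel, ls$stride, ls$padding,
                          ls$out_channels)
        h <- l$hout; w <- l$wout; cin <- ls$out_channels
        l
      },
      maxpool = {
        if (!spatial) stop("pool after flatten", call. = FALSE)
        l <- compile_pool(h, w, cin, ls$kernel, ls$stride)
        h <- l$hout; w <- l$wout
        l
      },
      lrn = {
        if (!spatial) stop("lrn after flatten", call. = FALSE)
        list(kind = "lrn", S = h * w, C = cin, n = ls$size,
             alpha = ls$alpha, beta = ls$beta, out_dim = h * w * cin)
      },
      fc = {
        din <- if (spatial) h * w * cin else din_prev
        spatial <- FALSE
        l <- list(kind = "fc", din = din, dout = ls$out_units,
                  out_dim = ls$out_units)
        l
      },
      relu = list(kind = "relu",
                  out_dim = if (spatial) h * w * cin else din_prev),
      dropout = list(kind = "dropout", p = ls$dropout_p,
                     out_dim = if (spatial) h * w * cin else din_prev),
      softmax = list(kind = "softmax",
                     out_dim = if (spatial) h * w * cin else din_prev),
      stop(sprintf("unknown layer kind '%s'", ls$kind), call. = FALSE)
    )
    lay$name <- ls$name
    layers[[length(layers) + 1]] <- lay
    din_prev <- lay$out_dim
  }
  list(input_dim = prod(spec$input_shape), layers = layers)
}

init_params <- function(compiled, seed) {
  with_seed(seed, lapply(compiled$layers, function(l) {
    if (l$kind == "conv") {
      list(W = matrix(rnorm(l$K * l$cout, sd = sqrt(2 / l$K)), l$K, l$cout),
           b = numeric(l$cout))
    } else if (l$kind == "fc") {
      list(W = matrix(rnorm(l$din * l$dout, sd = sqrt(2 / l$din)),
                      l$din, l$dout),
           b = numeric(l$dout))
    } else NULL
  }))
}

# ---- per-layer forward/backward -------------------------------------------

pad_rows <- function(M, l, fill) {
  if (is.null(l$origpos)) return(M)
  Mp <- matrix(fill, l$dpad, ncol(M))
  Mp[l$origpos, ] <- M
  Mp
}

unpad_rows <- function(Mp, l) {
  if (is.null(l$origpos)) Mp else Mp[l$origpos, , drop = FALSE]
}

# Compiled-kernel layer implementations. Reference pure-R versions
# (conv_fwd_ref etc.) are kept below and pinned to the kernels by a parity
# test.

conv_fwd <- function(M, l, par, keep_cache = TRUE) {
  Mp <- pad_rows(M, l, 0)
  r <- nn_conv_fwd(Mp, l$idx, par$W, par$b, keep_cache)
  list(out = r$out, cache = r$xcol)
}

conv_bwd <- function(dout, l, par, xcol) {
  r <- nn_conv_bwd(xcol, l$idx, par$W, dout, l$dpad)
  list(dX = unpad_rows(r$dX, l), dW = r$dW, db = as.vector(r$db))
}

pool_fwd <- function(M, l) {
  Mp <- pad_rows(M, l, -Inf)
  r <- nn_pool_fwd(Mp, l$idx)
  list(out = r$out, cache = r$amax)
}

pool_bwd <- function(dout, l, amax) {
  dMp <- nn_pool_bwd(dout, l$idx, amax, l$dpad)
  list(dX = unpad_rows(dMp, l))
}

# ---- pure-R reference implementations (oracles for the compiled kernels) ---

conv_fwd_ref <- function(M, l, par) {
  n <- ncol(M)
  Mp <- pad_rows(M, l, 0)
  xcol <- Mp[l$idx, , drop = FALSE]
  dim(xcol) <- c(l$K, l$P * n)
  z <- crossprod(par$W, xcol) + par$b
  a <- array(z, c(l$cout, l$hout, l$wout, n))
  out <- aperm(a, c(2, 3, 1, 4))
  dim(out) <- c(l$out_dim, n)
  list(out = out, cache = xcol)
}

conv_bwd_ref <- function(dout, l, par, xcol) {
  n <- ncol(dout)
  da <- array(dout, c(l$hout, l$wout, l$cout, n))
  dz <- aperm(da, c(3, 1, 2, 4))
  dim(dz) <- c(l$cout, l$P * n)
  dW <- tcrossprod(xcol, dz)
  db <- rowSums(dz)
  dxcol <- par$W %*% dz
  dim(dxcol) <- c(l$K * l$P, n)
  rs <- rowsum(dxcol, group = as.vector(l$idx))
  dMp <- matrix(0, l$dpad, n)
  dMp[as.integer(rownames(rs)), ] <- rs
  list(dX = unpad_rows(dMp, l), dW = dW, db = db)
}

pool_fwd_ref <- function(M, l) {
  n <- ncol(M)
  Mp <- pad_rows(M, l, -Inf)
  g <- Mp[l$idx, , drop = FALSE]
  dim(g) <- c(l$z2, l$Q * n)
  cur <- g[1, ]
  amax <- rep(1L, l$Q * n)
  for (k in 2:l$z2) {
    gk <- g[k, ]
    upd <- gk > cur
    cur[upd] <- gk[upd]
    amax[upd] <- k
  }
  list(out = matrix(cur, l$Q, n), cache = matrix(amax, l$Q, n))
}

pool_bwd_ref <- function(dout, l, amax) {
  n <- ncol(dout)
  amax <- as.vector(amax)
  qidx <- rep.int(0:(l$Q - 1), n)
  rowsel <- l$idx[amax + l$z2 * qidx]
  lin <- rowsel + l$dpad * rep(0:(n - 1), each = l$Q)
  rs <- rowsum(matrix(as.vector(dout)), group = lin)
  dMp <- matrix(0, l$dpad, n)
  dMp[as.numeric(rownames(rs))] <- rs
  list(dX = unpad_rows(dMp, l))
}

lrn_window_sum <- function(a, half) {
  # reference implementation (array layout S x C x N)
  s <- array(0, dim(a))
  C <- dim(a)[2]
  for (d in -half:half) {
    valid <- (1:C + d) >= 1 & (1:C + d) <= C
    s[, valid, ] <- s[, valid, , drop = FALSE] +
      a[, (1:C + d)[valid], , drop = FALSE]
  }
  s
}

lrn_fwd <- function(M, l) {
  half <- (l$n - 1) %/% 2
  ssum <- nn_lrn_wsum(M * M, l$S, l$C, half)
  scale <- 1 + (l$alpha / l$n) * ssum
  out <- M * scale^(-l$beta)
  list(out = out, cache = list(a = M, scale = scale, y = out))
}

lrn_bwd <- function(dout, l, cache) {
  half <- (l$n - 1) %/% 2
  tsum <- nn_lrn_wsum(dout * cache$y / cache$scale, l$S, l$C, half)
  dx <- dout * cache$scale^(-l$beta) -
    (2 * l$alpha * l$beta / l$n) * cache$a * tsum
  list(dX = dx)
}

# Full forward pass. `train` enables dropout (using the current RNG stream);
# `upto` stops after layer index `upto` and returns that activation.
# `engine = "reference"` selects the pure-R double-precision layer
# implementations (used by the parity and gradient-check tests).
net_forward <- function(M, compiled, params, train = FALSE, upto = NULL,
                        engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  compiled_eng <- engine == "compiled"
  caches <- vector("list", length(compiled$layers))
  for (i in seq_along(compiled$layers)) {
    l <- compiled$layers[[i]]
    par <- params[[i]]
    r <- switch(l$kind,
      conv = if (compiled_eng) conv_fwd(M, l, par, keep_cache = train || !is.null(upto))
             else conv_fwd_ref(M, l, par),
      maxpool = if (compiled_eng) pool_fwd(M, l) else pool_fwd_ref(M, l),
      lrn = lrn_fwd(M, l),
      fc = list(out = if (compiled_eng) {
        nn_sgemm(par$W, M, TRUE, FALSE) + par$b
      } else {
        crossprod(par$W, M) + par$b
      }, cache = M),
      relu = {
        out <- pmax(M, 0)
        list(out = out, cache = out > 0)
      },
      dropout = if (train) {
        mask <- matrix((runif(length(M)) >= l$p) / (1 - l$p),
                       nrow(M), ncol(M))
        list(out = M * mask, cache = mask)
      } else list(out = M, cache = NULL),
      softmax = list(out = softmax_cols(M), cache = NULL)
    )
    M <- r$out
    caches[[i]] <- r$cache
    if (!is.null(upto) && i == upto) return(list(out = M, caches = caches))
  }
  list(out = M, caches = caches)
}

softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(E))
}

# Backward from a gradient on the pre-softmax logits. Returns per-layer
# parameter gradients (NULL for parameterless layers).
net_backward <- function(dlogits, compiled, params, caches, n_layers,
                         engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  compiled_eng <- engine == "compiled"
  grads <- vector("list", length(compiled$layers))
  dM <- dlogits
  for (i in rev(seq_len(n_layers))) {
    l <- compiled$layers[[i]]
    par <- params[[i]]
    if (l$kind == "conv") {
      r <- if (compiled_eng) conv_bwd(dM, l, par, caches[[i]])
           else conv_bwd_ref(dM, l, par, caches[[i]])
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dM <- r$dX
    } else if (l$kind == "maxpool") {
      dM <- if (compiled_eng) pool_bwd(dM, l, caches[[i]])$dX
            else pool_bwd_ref(dM, l, caches[[i]])$dX
    } else if (l$kind == "lrn") {
      dM <- lrn_bwd(dM, l, caches[[i]])$dX
    } else if (l$kind == "fc") {
      X <- caches[[i]]
      if (compiled_eng) {
        grads[[i]] <- list(dW = nn_sgemm(X, dM, FALSE, TRUE), db = rowSums(dM))
        dM <- nn_sgemm(par$W, dM, FALSE, FALSE)
      } else {
        grads[[i]] <- list(dW = tcrossprod(X, dM), db = rowSums(dM))
        dM <- par$W %*% dM
      }
    } else if (l$kind == "relu") {
      dM <- dM * caches[[i]]
    } else if (l$kind == "dropout") {
      if (!is.null(caches[[i]])) dM <- dM * caches[[i]]
    }
  }
  grads
}
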
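# internal helpers shared across modules

ATTN_CONDITIONS <- c("LEFT", "RIGHT", "CENTER")

# Evaluate code under a fixed RNG seed without disturbing the caller's
# global random state.  Seeds are explicit arguments throughout the
# package; nothing relies on hidden global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

# Delay a per-scan label vector by `shift` scans: the instruction given at
# scan i is matched with the signal measured at scan i + shift, so the
# shifted label at scan i is the condition of scan i - shift.  The first
# `shift` scans have no shifted label (NA) and are dropped from rate
# denominators downstream.
shift_labels <- function(labels, shift) {
  stopifnot(shift >= 0)
  n <- length(labels)
  if (shift == 0) return(labels)
  if (shift >= n) return(rep(NA_character_, n))
  c(rep(NA_character_, shift), labels[seq_len(n - shift)])
}

# 1D Gaussian kernel truncated at 3 sigma (minimum radius 1)
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array with edge replication.
gaussian_blur3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  for (ax in 1:3) {
    vol <- aperm(vol, c(ax, setdiff(1:3, ax)))
    d <- dim(vol)
    m <- matrix(vol, nrow = d[1])
    out <- matrix(0, nrow = d[1], ncol = ncol(m))
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(d[1]) + o, 1L), d[1])
      out <- out + k[o + r + 1L] * m[idx, , drop = FALSE]
    }
    vol <- array(out, dim = d)
    vol <- aperm(vol, order(c(ax, setdiff(1:3, ax))))
  }
  vol
}

# Shift a logical 3D array by one voxel along axis `ax` in direction `dir`
# (+1/-1), padding with FALSE.  Used by morphological operations.
shift_logical3 <- function(x, ax, dir) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) {
    dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1L)
  } else {
    dst[[ax]] <- 1:(d[ax] - 1L); src[[ax]] <- 2:d[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(x) {
  out <- x
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    out <- out | shift_logical3(x, ax, dir)
  }
  out
}

# Fill enclosed cavities of a logical 3D mask: background connected to the
# array border (6-connectivity) stays background, everything else becomes
# foreground.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  reach <- bg & border
  repeat {
    grown <- dilate6(reach) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# Connected-component labels (6-connectivity) of a set of linear voxel
# indices within a grid of dimensions `dims`.  Returns an integer label per
# input index.  BFS over the (small) candidate set.
label_components6 <- function(idx, dims) {
  if (length(idx) == 0) return(integer(0))
  pos <- arrayInd(idx, dims)
  in_set <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = in_set)
  labels <- integer(length(idx))
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      p <- pos[v, ]
      for (o in 1:6) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > dims)) next
        lin <- q[1] + dims[1] * (q[2] - 1L) + dims[1] * dims[2] * (q[3] - 1L)
        j <- mget(as.character(lin), envir = in_set, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && labels[j] == 0L) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}
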
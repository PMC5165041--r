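# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_t1qc <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(paste0("t1qc_", class, "_error"),
                                         "t1qc_error"),
                      call = call))
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed; stays within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

# Extract the raw 3D array from a volume_grid or plain array.
vg_data <- function(x) {
  if (inherits(x, "volume_grid")) x$data else x
}

# Shift a 3D array by integer offsets (dx, dy, dz), zero-filling exposed
# planes. Used by the artifact injectors and morphological operators.
shift3d <- function(a, dx = 0L, dy = 0L, dz = 0L) {
  d <- dim(a)
  out <- array(0, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  src_x <- sx - dx; src_y <- sy - dy; src_z <- sz - dz
  kx <- src_x >= 1L & src_x <= d[1]
  ky <- src_y >= 1L & src_y <= d[2]
  kz <- src_z >= 1L & src_z <= d[3]
  if (!any(kx) || !any(ky) || !any(kz)) return(out)
  out[sx[kx], sy[ky], sz[kz]] <- a[src_x[kx], src_y[ky], src_z[kz]]
  out
}
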
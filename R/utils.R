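# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_rmquant <- function(msg, class) {
  rlang::abort(msg, class = c(class, "rmquant_error"))
}

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (length(x) == 0 || bad) {
    abort_rmquant(
      sprintf("`%s` must be %s", name, if (strict) "> 0" else ">= 0"),
      "rmquant_parameter_error"
    )
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort_rmquant(sprintf("`%s` must be TRUE or FALSE", name),
                  "rmquant_parameter_error")
  }
  invisible(x)
}

# Run `code` under a given RNG seed, restoring the caller's RNG state.
# All generators route randomness through this so repeat calls are
# bit-identical and never perturb the session RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, which
# shatters diagonal runs (fatal for 1-pixel skeletons); this merges its
# labels across diagonal adjacencies with a union-find pass.
bwlabel8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ny <- nrow(lab); nx <- ncol(lab)
  for (dc in c(-1L, 1L)) {
    rs <- 1:(ny - 1)
    cs <- if (dc == 1) 1:(nx - 1) else 2:nx
    a <- lab[rs, cs]
    b <- lab[rs + 1L, cs + dc]
    hit <- which(a > 0L & b > 0L & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, unique(roots))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# Derive a stream-specific child seed from a user seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}
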
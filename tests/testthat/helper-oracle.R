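# Independent oracles, deliberately avoiding the package's matrix/polynomial
# update path: plain logical evaluation straight from the edge lists, plus an
# explicit state-transition walk and a closed-form Welch t-test.

# one synchronous step by direct logical reading of the inhibitor-dominant
# rule from the subnetwork's edges (inputs from PKN in-degree)
oracle_next_state <- function(net, pkn, x, inputs_hold = TRUE) {
  nodes <- sort(pkn$nodes)
  nx <- x[nodes]
  for (v in nodes) {
    if (inputs_hold && !(v %in% pkn$edges$to)) {
      nx[v] <- x[[v]]
    } else {
      acts <- net$edges$from[net$edges$to == v & net$edges$sign > 0]
      inhs <- net$edges$from[net$edges$to == v & net$edges$sign < 0]
      nx[v] <- as.integer(any(x[acts] == 1L) && !any(x[inhs] == 1L))
    }
  }
  nx
}

# trajectory classification by walking the explicit transition sequence
oracle_classify <- function(net, pkn, x0, max_steps = 1000L, inputs_hold = TRUE) {
  nodes <- sort(pkn$nodes)
  x <- x0[nodes]
  seen <- list(paste(x, collapse = ""))
  steps <- 0L
  repeat {
    nx <- oracle_next_state(net, pkn, x, inputs_hold)
    if (all(nx == x)) return(list(outcome = "fixed_point", steps = steps, state = nx))
    steps <- steps + 1L
    key <- paste(nx, collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit))
      return(list(outcome = "cycle", steps = steps, cycle_length = steps - (hit - 1L)))
    if (steps >= max_steps) return(list(outcome = "truncated", steps = steps))
    seen[[length(seen) + 1L]] <- key
    x <- nx
  }
}

# all 2^n states of a node set, one named vector per row
all_states <- function(nodes) {
  n <- length(nodes)
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(m) <- nodes
  m
}

# closed-form Welch statistic (two-sided)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# tiny literal network builder for readable test setups
make_net <- function(from, sign, to, nodes = NULL) {
  signed_digraph(data.frame(from = from, sign = sign, to = to,
                            stringsAsFactors = FALSE), nodes = nodes)
}
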
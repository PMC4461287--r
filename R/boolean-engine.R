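#' Derive Boolean update rules from a pruned subnetwork
#'
#' Builds the inhibitor-dominant synchronous Boolean model of a subnetwork:
#' a node is active at the next step iff at least one of its retained
#' activators and none of its retained inhibitors are currently active. In
#' polynomial form, `x'_i = OR(activators) * (1 - OR(inhibitors))`, where OR
#' over an empty activator set is 0 and the inhibitor factor over an empty
#' inhibitor set is 1. A node whose regulators were all pruned away therefore
#' evaluates to constant 0 — pruning every edge is never a degenerate optimum.
#'
#' Input nodes — nodes with in-degree 0 in the ORIGINAL PKN, a property
#' recorded here and inherited by every subnetwork — represent external
#' stimuli and hold their state (`x' = x`) when `inputs_hold_state` is TRUE
#' (the default). Set it to FALSE to apply the strict rule everywhere.
#'
#' If both an activating and an inhibiting edge from u to v survive pruning,
#' u appears in both regulator sets and the inhibition dominates.
#'
#' @param pkn the reference prior-knowledge network (`signed_digraph`)
#' @param subnetwork a subnetwork of `pkn` (edges a subset, same node set);
#'   defaults to the PKN itself
#' @param inputs_hold_state logical; see above
#' @return object of class `rule_set`: per-node activator/inhibitor sets,
#'   `is_input` flags, and the 0/1 incidence matrices used for fast updates
#' @export
build_rules <- function(pkn, subnetwork = pkn, inputs_hold_state = TRUE) {
  if (!identical(sort(subnetwork$nodes), sort(pkn$nodes)))
    stop("subnetwork must keep the full PKN node set (pruning removes edges only)")
  extra <- setdiff(edge_keys(subnetwork), edge_keys(pkn))
  if (length(extra))
    stop("subnetwork has edge(s) absent from the PKN: ", paste(extra, collapse = ", "))
  nodes <- sort(pkn$nodes)
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  e <- subnetwork$edges
  act_mat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  inh_mat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(e)) {
    a <- e$sign > 0
    act_mat[cbind(idx[e$to[a]], idx[e$from[a]])] <- 1L
    inh_mat[cbind(idx[e$to[!a]], idx[e$from[!a]])] <- 1L
  }
  pe <- pkn$edges
  is_input <- !(nodes %in% pe$to)
  names(is_input) <- nodes
  activators <- lapply(nodes, function(v) sort(e$from[e$sign > 0 & e$to == v]))
  inhibitors <- lapply(nodes, function(v) sort(e$from[e$sign < 0 & e$to == v]))
  names(activators) <- names(inhibitors) <- nodes
  structure(list(nodes = nodes, activators = activators, inhibitors = inhibitors,
                 is_input = is_input, act_mat = act_mat, inh_mat = inh_mat,
                 inputs_hold_state = isTRUE(inputs_hold_state)),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d nodes (%d inputs%s)\n", length(x$nodes),
              sum(x$is_input),
              if (x$inputs_hold_state) ", holding state" else ", strict rule"))
  invisible(x)
}

#' Synchronous one-step update
#'
#' Applies the model's update functions to a network state: all nodes read
#' the current state and write the next one simultaneously. A pure function:
#' identical inputs give identical outputs.
#'
#' @param rules a `rule_set` from [build_rules()], or a `polynomial_rules`
#'   system with bespoke update functions (see [toy_boolean_system()])
#' @param x named 0/1 vector covering exactly the model's nodes
#' @return the next state, same names and order as `rules$nodes`
#' @export
update_state <- function(rules, x) UseMethod("update_state")

check_state <- function(rules, x) {
  missing <- setdiff(rules$nodes, names(x))
  if (length(missing))
    stop("state is missing gene(s): ", paste(missing, collapse = ", "))
  x <- x[rules$nodes]
  if (!all(x %in% c(0L, 1L))) stop("network state must be strictly 0/1")
  storage.mode(x) <- "integer"
  x
}

#' @export
update_state.rule_set <- function(rules, x) {
  x <- check_state(rules, x)
  act <- (rules$act_mat %*% x) > 0
  inh <- (rules$inh_mat %*% x) > 0
  nx <- as.integer(act & !inh)
  if (rules$inputs_hold_state) nx[rules$is_input] <- x[rules$is_input]
  stats::setNames(nx, rules$nodes)
}

#' @export
update_state.polynomial_rules <- function(rules, x) {
  x <- check_state(rules, x)
  stats::setNames(as.integer(rules$update(x)), rules$nodes)
}

#' Iterate synchronous updates to an attractor
#'
#' Runs the trajectory from `x0` until a fixed point (next state equals
#' current state), a cycle (next state equals a strictly earlier visited
#' state; detected by exact state hashing over the canonical sorted node
#' order), or the step cutoff. Trajectories exceeding `max_steps` (default
#' 1000) are reported as `truncated` and are discarded at scoring time.
#'
#' @param rules a `rule_set` or `polynomial_rules`
#' @param x0 named 0/1 initial state over the model's nodes
#' @param max_steps positive integer trajectory cutoff
#' @return object of class `trajectory_result`: `outcome` one of
#'   `"fixed_point"`, `"cycle"`, `"truncated"`; `attractor_state` (fixed
#'   points only); `steps_taken`; `cycle_length` (cycles only)
#' @export
run_to_attractor <- function(rules, x0, max_steps = 1000L) {
  stopifnot(max_steps >= 1L)
  x <- check_state(rules, x0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(x, collapse = ""), 0L, envir = seen)
  steps <- 0L
  repeat {
    nx <- update_state(rules, x)
    if (identical(unname(nx), unname(x))) {
      return(structure(list(outcome = "fixed_point", attractor_state = nx,
                            steps_taken = steps, cycle_length = NULL),
                       class = "trajectory_result"))
    }
    steps <- steps + 1L
    key <- paste(nx, collapse = "")
    first <- get0(key, envir = seen, ifnotfound = NULL)
    if (!is.null(first)) {
      return(structure(list(outcome = "cycle", attractor_state = NULL,
                            steps_taken = steps, cycle_length = steps - first),
                       class = "trajectory_result"))
    }
    if (steps >= max_steps) {
      return(structure(list(outcome = "truncated", attractor_state = NULL,
                            steps_taken = steps, cycle_length = NULL),
                       class = "trajectory_result"))
    }
    assign(key, steps, envir = seen)
    x <- nx
  }
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory: %s after %d step(s)%s\n", x$outcome, x$steps_taken,
              if (!is.null(x$cycle_length)) sprintf(" (period %d)", x$cycle_length) else ""))
  invisible(x)
}

#' Assemble an initial network state from a phenotype
#'
#' Genes with a known phenotype value (restricted to `known_genes` when the
#' training signal is partial) take that value; every other network node is
#' filled per `init_policy`: `"zero"` sets them to 0 (deterministic default),
#' `"random"` draws independent Bernoulli(0.5) states from the current RNG
#' stream.
#'
#' @param rules the model (`rule_set`) whose node set defines the state
#' @param phenotype named 0/1 vector (possibly covering non-network genes,
#'   which are ignored)
#' @param known_genes genes whose phenotype values may be used; defaults to
#'   all genes of `phenotype`
#' @param init_policy `"zero"` or `"random"`
#' @return named 0/1 vector over `rules$nodes`
#' @export
initial_state <- function(rules, phenotype, known_genes = names(phenotype),
                          init_policy = c("zero", "random")) {
  init_policy <- match.arg(init_policy)
  n <- length(rules$nodes)
  x <- if (init_policy == "zero") rep(0L, n)
       else as.integer(stats::runif(n) < 0.5)
  names(x) <- rules$nodes
  use <- intersect(intersect(names(phenotype), known_genes), rules$nodes)
  x[use] <- as.integer(phenotype[use])
  x
}

#' Export update rules as a human-readable file
#'
#' One line per node, `node = (g1 | g2) & !(g3 | g4)`, with `INPUT` marking
#' input nodes that hold their state and `0` marking regulated nodes whose
#' activators were all pruned.
#'
#' @param rules a `rule_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_rules <- function(rules, path) {
  writeLines(format_rules(rules), path)
  invisible(path)
}

#' @rdname write_rules
#' @return `format_rules`: character vector, one formula per node
#' @export
format_rules <- function(rules) {
  vapply(rules$nodes, function(v) {
    if (rules$is_input[[v]] && rules$inputs_hold_state)
      return(sprintf("%s = %s  # INPUT", v, v))
    a <- rules$activators[[v]]
    i <- rules$inhibitors[[v]]
    rhs <- if (!length(a)) "0"
           else if (length(i)) sprintf("(%s) & !(%s)", paste(a, collapse = " | "),
                                       paste(i, collapse = " | "))
           else sprintf("(%s)", paste(a, collapse = " | "))
    sprintf("%s = %s", v, rhs)
  }, character(1), USE.NAMES = FALSE)
}
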
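## One-rate Mk ("Mk1") model for a binary character on a tree: a symmetric
## two-state continuous-time Markov chain with a single rate q governing both
## 0->1 and 1->0 change. Likelihoods use Felsenstein pruning with per-node
## rescaling; marginal reconstructions use the standard down-pass/up-pass.
## When node ages are available the tree is treated as time-scaled (q in
## events per Gy), matching reconstruction on a chronogram.

LOGLIK_FLOOR <- -1e10

#' Mk1 transition probability matrix
#'
#' For the symmetric binary chain, \eqn{P(stay) = (1 + e^{-2qt})/2} and
#' \eqn{P(change) = (1 - e^{-2qt})/2}.
#'
#' @param q change rate (> 0, per unit branch length).
#' @param t branch length (>= 0).
#' @return 2x2 matrix, rows = from-state (0,1), rows sum to 1.
#' @export
mk1_transition <- function(q, t) {
  if (t < 0) stop("domain error: negative branch length")
  if (q < 0) stop("domain error: negative rate")
  stay <- 0.5 * (1 + exp(-2 * q * t))
  matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

## tip states as a named 0/1 vector aligned to tree taxa
check_tip_states <- function(tree, tips) {
  ph <- tree$phylo
  missing <- setdiff(ph$tip.label, names(tips))
  if (length(missing))
    stop("validation error: leaves without a state: ",
         paste(missing, collapse = ", "))
  s <- as.integer(tips[ph$tip.label])
  if (any(is.na(s)) || any(!s %in% c(0L, 1L)))
    stop("validation error: tip states must be 0 or 1")
  s
}

## pruning pass: per-node conditional likelihoods with rescaling.
## Returns list(partial = (N x 2), logscale = numeric(N)).
mk1_down_pass <- function(tree, states, q) {
  ph <- tree$phylo
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  dur <- branch_durations(tree)
  partial <- matrix(1, N, 2)
  logscale <- numeric(N)
  partial[seq_len(n), ] <- 0
  partial[cbind(seq_len(n), states + 1L)] <- 1
  po <- ape::postorder(ph)
  for (i in po) {
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    P <- mk1_transition(q, dur[i])
    contrib <- P %*% partial[ch, ]
    partial[p, ] <- partial[p, ] * contrib
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(partial[p, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      partial[p, ] <- partial[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  list(partial = partial, logscale = logscale, dur = dur)
}

#' Mk1 log-likelihood of binary tip states
#'
#' Felsenstein pruning; equals the log of the sum over all ancestral state
#' assignments of the product of transition probabilities times the root prior.
#' Degenerate likelihood-zero cases are floored at -1e10.
#'
#' @param tree a \code{dated_tree} with node ages or branch lengths.
#' @param tips named 0/1 vector over all leaf labels.
#' @param q Mk1 rate (> 0; q = 0 is accepted and handled as the no-change
#'   degenerate limit).
#' @param root_prior probability of state 1 at the root (default 0.5, the Mk1
#'   stationary distribution).
#' @return log-likelihood (scalar).
#' @export
mk1_loglik <- function(tree, tips, q, root_prior = 0.5) {
  states <- check_tip_states(tree, tips)
  dp <- mk1_down_pass(tree, states, q)
  r <- root_node(tree$phylo)
  lik <- sum(c(1 - root_prior, root_prior) * dp$partial[r, ])
  if (lik <= 0) return(LOGLIK_FLOOR)
  max(log(lik) + dp$logscale[r], LOGLIK_FLOOR)
}

#' Fit the Mk1 rate by maximum likelihood
#'
#' Bounded scalar maximization of \code{\link{mk1_loglik}} over
#' \code{q in [1e-8, q_max]} with restarts from \code{c(0.01, 0.1, 1)/depth}
#' (depth = root-to-tip time span). Monomorphic tip data sit on the lower
#' boundary and are flagged.
#'
#' @param tree a \code{dated_tree}.
#' @param tips named 0/1 tip states.
#' @param root_prior root prior for state 1.
#' @param q_max upper bound for the rate search.
#' @param tol optimizer tolerance.
#' @return list with \code{q}, \code{loglik}, \code{boundary} (logical),
#'   \code{convergence} ("ok" or "boundary").
#' @export
fit_q <- function(tree, tips, root_prior = 0.5, q_max = NULL, tol = 1e-8) {
  states <- check_tip_states(tree, tips)
  depth <- max(node_depths(tree))
  if (is.null(q_max)) q_max <- 1000 / depth
  q_min <- 1e-8
  if (length(unique(states)) == 1L) {
    return(list(q = q_min, loglik = mk1_loglik(tree, tips, q_min, root_prior),
                boundary = TRUE, convergence = "boundary"))
  }
  f <- function(lq) mk1_loglik(tree, tips, exp(lq), root_prior)
  best <- NULL
  starts <- c(0.01, 0.1, 1.0) / depth
  for (s in starts) {
    # bracket around each start, then refine over the full bound
    opt <- optimize(f, interval = log(c(q_min, q_max)), maximum = TRUE,
                    tol = tol)
    cand <- list(q = exp(opt$maximum), loglik = opt$objective)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
    # local polish from the start point
    lo <- log(max(q_min, s / 50)); hi <- log(min(q_max, s * 50))
    if (hi > lo) {
      opt2 <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
      cand2 <- list(q = exp(opt2$maximum), loglik = opt2$objective)
      if (cand2$loglik > best$loglik) best <- cand2
    }
  }
  bnd <- best$q <= q_min * 1.01 || best$q >= q_max * 0.99
  list(q = best$q, loglik = best$loglik, boundary = bnd,
       convergence = if (bnd) "boundary" else "ok")
}

node_depths <- function(tree) {
  if (!is.null(tree$node_ages)) return(max(tree$node_ages) - tree$node_ages)
  ph <- tree$phylo
  depth <- numeric(length(ph$tip.label) + ph$Nnode)
  for (i in rev(ape::postorder(ph)))
    depth[ph$edge[i, 2]] <- depth[ph$edge[i, 1]] + ph$edge.length[i]
  depth
}

#' Marginal ancestral state reconstruction under Mk1
#'
#' Computes, for every node, the marginal probability that the character is in
#' state 1 (gene present), integrating over all other nodes' states, via the
#' standard down-pass/up-pass. Each node is called \code{present} when
#' \code{P(1) >= present_threshold}, \code{absent} when
#' \code{P(1) <= absent_threshold}, else \code{ambiguous}.
#'
#' @param tree a \code{dated_tree}.
#' @param tips named 0/1 tip states.
#' @param q Mk1 rate; when \code{NULL} (default) the rate is fitted with
#'   \code{\link{fit_q}}.
#' @param root_prior probability of state 1 at the root.
#' @param present_threshold,absent_threshold decision thresholds on P(1).
#' @return an \code{asr_result}: data.frame \code{nodes} (node, label,
#'   p_present, decision) plus \code{q}, \code{loglik}, thresholds.
#' @export
marginal_asr <- function(tree, tips, q = NULL, root_prior = 0.5,
                         present_threshold = 0.7, absent_threshold = 0.3) {
  states <- check_tip_states(tree, tips)
  fit <- NULL
  if (is.null(q)) {
    fit <- fit_q(tree, tips, root_prior)
    q <- fit$q
  }
  ph <- tree$phylo
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  dp <- mk1_down_pass(tree, states, q)
  r <- root_node(ph)
  prior <- c(1 - root_prior, root_prior)
  tot_log <- {
    lik <- sum(prior * dp$partial[r, ])
    if (lik <= 0) LOGLIK_FLOOR else log(lik) + dp$logscale[r]
  }

  # up-pass: U[v,s] = likelihood of everything outside the subtree of v,
  # given state s at v (including the branch above v).
  up <- matrix(NA_real_, N, 2)
  up_scale <- numeric(N)
  up[r, ] <- prior
  edges_of <- split(seq_len(nrow(ph$edge)), ph$edge[, 1])
  for (i in rev(ape::postorder(ph))) {     # preorder over edges
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    sibs <- setdiff(edges_of[[as.character(p)]], i)
    sib_msg <- c(1, 1)
    sib_log <- 0
    for (j in sibs) {
      b <- ph$edge[j, 2]
      Pj <- mk1_transition(q, dp$dur[j])
      sib_msg <- sib_msg * as.vector(Pj %*% dp$partial[b, ])
      sib_log <- sib_log + dp$logscale[b]
    }
    Pv <- mk1_transition(q, dp$dur[i])
    # sum over parent state: U[p, sp] * sib_msg[sp] * P(sp -> sc)
    up[ch, ] <- as.vector(t(Pv) %*% (up[p, ] * sib_msg))
    up_scale[ch] <- up_scale[p] + sib_log
    m <- max(up[ch, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      up[ch, ] <- up[ch, ] / m
      up_scale[ch] <- up_scale[ch] + log(m)
    }
  }

  p1 <- numeric(N)
  for (v in seq_len(N)) {
    w <- up[v, ] * dp$partial[v, ]
    p1[v] <- if (sum(w) > 0) w[2] / sum(w) else NA_real_
  }
  p1[seq_len(n)] <- states  # tips are observed

  labels <- c(ph$tip.label,
              if (!is.null(ph$node.label)) ph$node.label else
                paste0("node", seq_len(ph$Nnode) + n))
  labels[n + seq_len(ph$Nnode)] <- ifelse(
    nzchar(labels[n + seq_len(ph$Nnode)]),
    labels[n + seq_len(ph$Nnode)], paste0("node", n + seq_len(ph$Nnode)))
  decision <- ifelse(p1 >= present_threshold, "present",
                     ifelse(p1 <= absent_threshold, "absent", "ambiguous"))
  structure(list(
    nodes = data.frame(node = seq_len(N), label = labels, p_present = p1,
                       decision = decision, stringsAsFactors = FALSE),
    q = q, loglik = tot_log, fit = fit,
    present_threshold = present_threshold,
    absent_threshold = absent_threshold,
    tree = tree), class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Mk1 marginal ASR: q =", signif(x$q, 4), " logLik =",
      signif(x$loglik, 6), "\n")
  print(head(x$nodes[x$nodes$node > sum(x$nodes$decision %in% c("present", "absent", "ambiguous")) / 2, ], 10))
  invisible(x)
}

#' Candidate gene-gain edges from an ancestral reconstruction
#'
#' Returns every edge whose parent is called absent or ambiguous while the
#' child is called present: the signature of a gene acquired along that branch
#' (a candidate lateral transfer into the subtended clade).
#'
#' @param asr an \code{asr_result} from \code{\link{marginal_asr}}.
#' @return data.frame with columns parent, child, parent_decision and a list
#'   column \code{taxa} (the taxon set subtended by the child).
#' @export
candidate_gain_edges <- function(asr) {
  tree <- asr$tree
  ph <- tree$phylo
  dec <- asr$nodes$decision
  st <- subtended_taxa(ph)
  keep <- which(dec[ph$edge[, 1]] %in% c("absent", "ambiguous") &
                dec[ph$edge[, 2]] == "present")
  out <- data.frame(parent = ph$edge[keep, 1], child = ph$edge[keep, 2],
                    parent_decision = dec[ph$edge[keep, 1]],
                    stringsAsFactors = FALSE)
  out$taxa <- lapply(out$child, function(v) st[[v]])
  out
}
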
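## Penalized-likelihood rate smoothing: convert substitution branch lengths
## into node ages under min/max age constraints. The criterion is Sanderson's:
## a Poisson log-likelihood of each branch's expected substitutions given
## rate x duration, minus lambda times a roughness penalty on rate changes
## between parent and child branches (plus the variance of the rates of the
## root's child branches, which have no parent branch).

#' Penalized-likelihood objective
#'
#' \deqn{\Phi = \sum_e [x_e \log\mu_e - \mu_e] - \lambda\Big(\sum_{e'} (r_{e'} -
#' r_{pa(e')})^2 + \mathrm{Var}(r_{root\,children})\Big)}
#' with \eqn{x_e = \ell_e L} (branch length times alignment length, the
#' estimated substitution count) and \eqn{\mu_e = r_e d_e L} (rate times
#' duration times alignment length). Larger is better. A zero-duration branch
#' with nonzero length is an impossible point and returns \code{-Inf}.
#'
#' @param tree a \code{dated_tree} whose \code{phylo$edge.length} are
#'   substitution lengths per site.
#' @param ages numeric node-age vector (Ga), ape node indexing.
#' @param rates per-edge substitution rates (per site per Gy), parallel to
#'   \code{tree$phylo$edge}.
#' @param lambda smoothing weight (>= 0).
#' @param sites effective alignment length L (scales the data likelihood).
#' @return scalar objective value.
#' @export
pl_objective <- function(tree, ages, rates, lambda, sites = 1000) {
  ph <- tree$phylo
  if (is.null(ph$edge.length)) stop("tree has no branch lengths")
  if (any(rates <= 0)) return(-Inf)
  dur <- ages[ph$edge[, 1]] - ages[ph$edge[, 2]]
  if (any(dur < 0)) return(-Inf)
  x <- ph$edge.length * sites
  mu <- rates * dur * sites
  if (any(mu <= 0 & x > 0)) return(-Inf)
  pos <- x > 0
  ll <- sum(x[pos] * log(mu[pos])) - sum(mu)
  # roughness penalty over edges with a parent edge
  parent_edge <- match(ph$edge[, 1], ph$edge[, 2])
  has_parent <- !is.na(parent_edge)
  pen <- sum((rates[has_parent] - rates[parent_edge[has_parent]])^2)
  root_children <- which(!has_parent)
  if (length(root_children) > 1) pen <- pen + var(rates[root_children])
  ll - lambda * pen
}

#' Propagate age constraints to per-node bounds
#'
#' Each node's feasible interval is tightened by its own constraint, the
#' maxima of all its ancestors and the minima of all its descendants. Tips are
#' fixed at age 0. Infeasibility (empty interval) is detected here.
#'
#' @param tree a \code{dated_tree} with clade labels covering the constraint
#'   clades.
#' @param constraints data.frame with columns clade, min_age, max_age (Ga),
#'   as from \code{\link{read_age_constraints}}.
#' @return matrix with columns \code{lo}, \code{hi}, one row per node.
#' @export
propagate_constraints <- function(tree, constraints) {
  ph <- tree$phylo
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  lo <- rep(0, N); hi <- rep(Inf, N)
  hi[seq_len(n)] <- 0            # extant tips
  node_of <- character(N)
  if (nrow(constraints)) {
    for (k in seq_len(nrow(constraints))) {
      v <- resolve_clade(tree, constraints$clade[k])
      if (!is.na(constraints$min_age[k]))
        lo[v] <- max(lo[v], constraints$min_age[k])
      if (!is.na(constraints$max_age[k]))
        hi[v] <- min(hi[v], constraints$max_age[k])
      node_of[v] <- constraints$clade[k]
    }
  }
  # maxima flow root-down, minima flow tip-up
  po <- ape::postorder(ph)
  for (i in rev(po)) {           # preorder: tighten child hi by parent hi
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    hi[ch] <- min(hi[ch], hi[p])
  }
  for (i in po) {                # postorder: tighten parent lo by child lo
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    lo[p] <- max(lo[p], lo[ch])
  }
  bad <- which(lo > hi + 1e-12)
  if (length(bad)) {
    labs <- ifelse(nzchar(node_of[bad]), node_of[bad], paste0("node", bad))
    stop("constraint-conflict error: infeasible age bounds at ",
         paste(unique(labs), collapse = ", "))
  }
  cbind(lo = lo, hi = hi)
}

logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

## decode parameter vector into ages (preorder fractional placement) + rates
pl_decode <- function(theta, ph, bounds, eps) {
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  internals <- (n + 1L):N
  th_age <- theta[seq_along(internals)]
  th_rate <- theta[-seq_along(internals)]
  ages <- numeric(N)
  r <- root_node(ph)
  ord <- c(r, ph$edge[rev(ape::postorder(ph)), 2])     # preorder nodes
  ord <- ord[ord > n]
  parent <- rep(NA_integer_, N)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  ok <- TRUE
  idx <- match(ord, internals)
  for (k in seq_along(ord)) {
    v <- ord[k]
    lo <- bounds[v, "lo"]
    hi <- bounds[v, "hi"]
    if (!is.na(parent[v])) hi <- min(hi, ages[parent[v]] - eps)
    if (!is.finite(hi)) hi <- max(lo * 10, 10)  # unconstrained top: soft cap
    if (hi < lo - 1e-9) { ok <- FALSE; hi <- lo }
    if (hi - lo < 1e-9) ages[v] <- (lo + hi) / 2   # pinned age
    else ages[v] <- lo + logistic(th_age[idx[k]]) * (hi - lo)
  }
  list(ages = ages, rates = exp(th_rate), ok = ok)
}

## encode an age/rate configuration into theta (inverse of pl_decode)
pl_encode <- function(ages, rates, ph, bounds, eps) {
  n <- length(ph$tip.label)
  N <- n + ph$Nnode
  internals <- (n + 1L):N
  parent <- rep(NA_integer_, N)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  ord <- c(root_node(ph), ph$edge[rev(ape::postorder(ph)), 2])
  ord <- ord[ord > n]
  th <- numeric(length(internals))
  idx <- match(ord, internals)
  for (k in seq_along(ord)) {
    v <- ord[k]
    lo <- bounds[v, "lo"]; hi <- bounds[v, "hi"]
    if (!is.na(parent[v])) hi <- min(hi, ages[parent[v]] - eps)
    if (!is.finite(hi)) hi <- max(lo * 10, 10)
    f <- if (hi - lo < 1e-9) 0.5 else (ages[v] - lo) / (hi - lo)
    th[idx[k]] <- logit(min(max(f, 1e-6), 1 - 1e-6))
  }
  c(th, log(rates))
}

#' Date a tree by penalized likelihood
#'
#' Maximizes \code{\link{pl_objective}} over internal node ages and per-branch
#' rates, subject to the propagated constraint box and strict parent > child
#' ordering (enforced by construction, margin \code{eps}). Ages are
#' parameterized as logistic fractions of each node's feasible interval
#' (placed root-down), rates on the log scale; optimization is quasi-Newton
#' (BFGS) from a path-length-proportional initialization with random restarts.
#'
#' @param tree a \code{dated_tree} with substitution branch lengths.
#' @param constraints age-constraint data.frame (clade, min_age, max_age). At
#'   least one finite maximum (typically on the root) is required to set the
#'   absolute scale.
#' @param lambda smoothing weight (default 10).
#' @param sites effective alignment length (default 1000).
#' @param restarts number of jittered restarts (default 5).
#' @param seed RNG seed for the restarts (default 1).
#' @param eps strict-inequality margin in Ga (default 1e-6).
#' @return a \code{chronogram}: the input \code{dated_tree} with
#'   \code{node_ages} filled, plus per-edge \code{rates}, \code{objective},
#'   \code{lambda} and the \code{seed} used.
#' @export
date_tree <- function(tree, constraints, lambda = 10, sites = 1000,
                      restarts = 5, seed = 1, eps = 1e-6) {
  ph <- tree$phylo
  if (is.null(ph$edge.length)) stop("dating requires branch lengths")
  bounds <- propagate_constraints(tree, constraints)
  r <- root_node(ph)
  if (!is.finite(bounds[r, "hi"]))
    stop("dating refuses to run: no finite maximum constrains the root ",
         "(no absolute time scale)")
  n <- length(ph$tip.label)

  # initialization: node depth fraction of the deepest path, scaled to a
  # root age at the middle of its feasible interval, clipped into each box
  depth <- node_depths(dated_tree(ph))
  root_init <- if (bounds[r, "lo"] > 0)
    (bounds[r, "lo"] + bounds[r, "hi"]) / 2 else bounds[r, "hi"] * 0.75
  frac <- depth / max(depth[r], 1e-12)
  ages0 <- frac * root_init
  ages0[seq_len(n)] <- 0
  parent <- rep(NA_integer_, n + ph$Nnode)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  ord <- c(r, ph$edge[rev(ape::postorder(ph)), 2]); ord <- ord[ord > n]
  for (v in ord) {
    hi <- bounds[v, "hi"]
    if (!is.na(parent[v])) hi <- min(hi, ages0[parent[v]] - eps)
    ages0[v] <- min(max(ages0[v], bounds[v, "lo"] + eps), hi - eps)
    if (ages0[v] <= bounds[v, "lo"]) ages0[v] <- bounds[v, "lo"] + (hi - bounds[v, "lo"]) / 2
  }
  dur0 <- ages0[ph$edge[, 1]] - ages0[ph$edge[, 2]]
  rate0 <- sum(ph$edge.length) / max(sum(dur0), 1e-12)
  theta0 <- pl_encode(ages0, rep(rate0, nrow(ph$edge)), ph, bounds, eps)

  negobj <- function(theta) {
    dec <- pl_decode(theta, ph, bounds, eps)
    if (!dec$ok) return(1e12)
    val <- pl_objective(tree, dec$ages, dec$rates, lambda, sites)
    if (!is.finite(val)) return(1e12)
    -val
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  best <- NULL
  for (k in seq_len(max(1, restarts))) {
    th <- if (k == 1) theta0 else theta0 + rnorm(length(theta0), sd = 0.5)
    fit <- tryCatch(
      optim(th, negobj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # polish with Nelder-Mead to escape flat BFGS stalls
    fit2 <- optim(fit$par, negobj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    if (fit2$value < fit$value) fit <- fit2
    fit3 <- tryCatch(
      optim(fit$par, negobj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit3) && fit3$value < fit$value) fit <- fit3
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("penalized-likelihood optimization failed")
  dec <- pl_decode(best$par, ph, bounds, eps)

  # hard post-hoc constraint verification
  viol <- dec$ages < bounds[, "lo"] - 1e-6 | dec$ages > bounds[, "hi"] + 1e-6
  if (any(viol))
    stop("internal error: dated ages violate constraints at node(s) ",
         paste(which(viol), collapse = ", "))

  out <- tree
  out$node_ages <- dec$ages
  out$rates <- dec$rates
  out$objective <- -best$value
  out$lambda <- lambda
  out$seed <- seed
  class(out) <- c("chronogram", class(tree))
  out
}
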
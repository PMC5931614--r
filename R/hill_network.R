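## Hill-function gene-circuit models.
##
## A network is a set of genes, a set of directed regulatory paths (each an
## activator or a repressor with its own Hill parameters), first-order
## degradation per gene, and an optional constitutive (basal) production rate
## per gene.  The production rate of a gene is
##
##   (basal + sum_i a_i c_A(K_i, n_i, x_i)) * prod_j c_R(K_j, n_j, x_j)
##
## with c_A = (Kx)^n / (1 + (Kx)^n) and c_R = 1 / (1 + (Kx)^n), so K = 0
## deletes a path (c_A = 0, c_R = 1).  The basal rate sits inside the
## activator sum and is therefore subject to repression; it is what lets a
## repressor-only gene produce anything at all.

#' Hill activator activity
#'
#' Fractional activity \eqn{(Kx)^n / (1 + (Kx)^n)} of a transcriptional
#' activator at concentration `x`.  Returns exactly 0 when `K = 0`: a zero
#' association constant encodes the absence of the regulatory path.
#'
#' @param K Association constant (1/concentration), `K >= 0`.
#' @param n Hill coefficient, `n > 0`.
#' @param x Regulator concentration, `x >= 0`.  Vectorized.
#' @return Activity in `[0, 1]`.
#' @seealso [repressor_activity()], [production_rate()]
#' @export
#' @examples
#' activator_activity(1, 1, 1)      # half-saturation: 0.5
#' activator_activity(0, 4, 100)    # absent path: 0
activator_activity <- function(K, n, x) {
  z <- K * pmax(x, 0)
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- 1 / (1 + exp(-n[if (length(n) > 1) pos else 1] * log(z[pos])))
  out
}

#' Hill repressor activity
#'
#' Fractional activity \eqn{1 / (1 + (Kx)^n)} of a transcriptional repressor.
#' Returns exactly 1 when `K = 0` (no repression).
#'
#' @inheritParams activator_activity
#' @return Activity in `(0, 1]`.
#' @export
#' @examples
#' repressor_activity(1, 1, 1)   # 0.5
#' repressor_activity(0, 2, 10)  # absent path: 1
repressor_activity <- function(K, n, x) {
  z <- K * pmax(x, 0)
  out <- rep(1, length(z))
  pos <- z > 0
  out[pos] <- 1 / (1 + exp(n[if (length(n) > 1) pos else 1] * log(z[pos])))
  out
}

#' Construct a regulatory-path table
#'
#' @param source,target Gene names (or indices) of regulator and regulated gene.
#' @param sign `"activator"` or `"repressor"`.
#' @param K Association constant, `>= 0`.
#' @param n Hill coefficient.
#' @param a Maximal production amplitude; activator paths only (`NA` for
#'   repressors).
#' @return A one-row `data.frame` suitable for [hill_network()].
#' @export
regulatory_path <- function(source, target, sign = c("activator", "repressor"),
                            K, n = 2, a = NA_real_) {
  sign <- match.arg(sign)
  if (sign == "repressor" && !is.na(a))
    emps_error("emps_contract", "repressor paths carry no amplitude 'a'")
  data.frame(source = source, target = target, sign = sign,
             K = K, n = n, a = a, stringsAsFactors = FALSE)
}

#' Build a Hill gene-network model
#'
#' @param genes Character vector of gene names (order fixes the state order).
#' @param paths `data.frame` with columns `source`, `target`, `sign`, `K`,
#'   `n`, `a` (rows from [regulatory_path()], row-bound).  May be empty.
#' @param degradation First-order degradation rate constant per gene (1/time),
#'   recycled; all `> 0`.
#' @param basal Constitutive production rate per gene (concentration/time),
#'   recycled; `>= 0`.  The basal term is multiplied by the gene's repressor
#'   activities, like a constitutive activator input.
#' @return An object of class `hill_network` with a canonically numbered path
#'   table (see [build_redundant_model()] for the numbering rule).
#' @export
hill_network <- function(genes, paths = NULL, degradation = 0.2, basal = 0) {
  genes <- as.character(genes)
  G <- length(genes)
  if (G < 1) emps_error("emps_contract", "need at least one gene")
  if (is.null(paths) || nrow(paths) == 0) {
    paths <- data.frame(source = character(), target = character(),
                        sign = character(), K = numeric(), n = numeric(),
                        a = numeric(), stringsAsFactors = FALSE)
  }
  paths$source <- as.character(paths$source)
  paths$target <- as.character(paths$target)
  if (!all(paths$source %in% genes) || !all(paths$target %in% genes))
    emps_error("emps_contract", "path source/target must name declared genes")
  if (!all(paths$sign %in% c("activator", "repressor")))
    emps_error("emps_contract", "path sign must be 'activator' or 'repressor'")
  if (any(paths$K < 0)) emps_error("emps_contract", "association constants must be >= 0")
  if (any(paths$sign == "activator" & !is.finite(paths$a)))
    emps_error("emps_contract", "activator paths need a finite amplitude 'a'")
  degradation <- rep_len(degradation, G)
  basal <- rep_len(basal, G)
  if (any(degradation <= 0)) emps_error("emps_contract", "degradation rates must be > 0")
  if (any(basal < 0)) emps_error("emps_contract", "basal rates must be >= 0")
  ## canonical ordering: targets-major, then sources, then activator before
  ## repressor; path_id is the rank within the full 2*G^2 enumeration so that
  ## sparse sub-circuits keep the ids they have inside the redundant model
  ti <- match(paths$target, genes); si <- match(paths$source, genes)
  sgn <- ifelse(paths$sign == "activator", 0L, 1L)
  paths$path_id <- (ti - 1L) * 2L * G + (si - 1L) * 2L + sgn + 1L
  paths <- paths[order(paths$path_id), , drop = FALSE]
  if (anyDuplicated(paths$path_id))
    emps_error("emps_contract", "duplicate (source, target, sign) path")
  rownames(paths) <- NULL
  structure(list(genes = genes,
                 paths = paths[, c("path_id", "source", "target", "sign", "K", "n", "a")],
                 degradation = setNames(degradation, genes),
                 basal = setNames(basal, genes)),
            class = "hill_network")
}

#' @export
print.hill_network <- function(x, ...) {
  cat(sprintf("<hill_network> %d genes (%s), %d paths\n",
              length(x$genes), paste(x$genes, collapse = ", "), nrow(x$paths)))
  if (nrow(x$paths)) print(x$paths, row.names = FALSE)
  cat("degradation:", paste(sprintf("%s=%.4g", x$genes, x$degradation), collapse = " "), "\n")
  cat("basal:      ", paste(sprintf("%s=%.4g", x$genes, x$basal), collapse = " "), "\n")
  invisible(x)
}

#' Fully connected "redundant" network
#'
#' Builds the over-complete model in which every gene may activate and repress
#' every gene (including itself): `2 * G^2` candidate paths for `G` genes.
#' Sparse regularization of the association constants prunes this model down
#' to the data-supported topology.
#'
#' Path numbering is targets-major, then sources, then sign with activator
#' before repressor, 1-based.  For genes (X, Y, Z): path 1 = X activates X,
#' path 2 = X represses X, path 3 = Y activates X, ..., path 18 = Z represses
#' Z.  The numbering is stable and emitted in all reports.
#'
#' @param genes Gene names, or a single integer count (names `g1`, `g2`, ...).
#' @param K,n,a Initial Hill parameters given to every candidate path.
#' @param degradation,basal Initial per-gene rates (recycled).
#' @return A `hill_network` with `2 * G^2` paths.
#' @export
#' @examples
#' nrow(build_redundant_model(3)$paths)  # 18
build_redundant_model <- function(genes, K = 0.5, n = 2, a = 1,
                                  degradation = 0.2, basal = 0.1) {
  if (is.numeric(genes) && length(genes) == 1)
    genes <- paste0("g", seq_len(genes))
  G <- length(genes)
  grid <- expand.grid(sign = c("activator", "repressor"), source = genes,
                      target = genes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  paths <- data.frame(source = grid$source, target = grid$target,
                      sign = grid$sign, K = K, n = n,
                      a = ifelse(grid$sign == "activator", a, NA_real_),
                      stringsAsFactors = FALSE)
  hill_network(genes, paths, degradation = degradation, basal = basal)
}

#' Production rate of one gene (redundant-model kinetics)
#'
#' Sum of amplitude-weighted activator activities (plus the basal rate) times
#' the product of repressor activities, for the paths targeting one gene.
#'
#' @param target_paths Path table rows sharing a single target gene.
#' @param x Named state vector (names = gene names) or numeric vector indexed
#'   like the `source` entries.
#' @param basal Basal production rate of the target gene.
#' @return Production rate (concentration/time).
#' @export
production_rate <- function(target_paths, x, basal = 0) {
  if (nrow(target_paths) && length(unique(target_paths$target)) != 1L)
    emps_error("emps_contract", "paths must share one target gene")
  xs <- function(src) if (!is.null(names(x))) x[[src]] else x[[as.integer(src)]]
  act <- basal
  rep_ <- 1
  for (i in seq_len(nrow(target_paths))) {
    p <- target_paths[i, ]
    if (p$sign == "activator")
      act <- act + p$a * activator_activity(p$K, p$n, xs(p$source))
    else
      rep_ <- rep_ * repressor_activity(p$K, p$n, xs(p$source))
  }
  act * rep_
}

#' Embed a circuit into a larger gene set
#'
#' Re-expresses a sparse circuit over a superset of genes: existing paths
#' keep their kinetics (path ids are renumbered by the canonical enumeration
#' over the full gene set), added genes are inert — no regulation, zero
#' basal production, first-order decay at `degradation_fill`.  Used to state
#' a ground-truth circuit as a sparse subset of the redundant model over more
#' nodes, e.g. when inferring how many genes a network actually needs.
#'
#' @param net A `hill_network`.
#' @param genes Superset of `net$genes` (order defines the new state order).
#' @param degradation_fill Decay rate given to the added inert genes.
#' @return A `hill_network` over `genes`.
#' @export
embed_network <- function(net, genes, degradation_fill = 0.3) {
  if (!all(net$genes %in% genes))
    emps_error("emps_contract", "genes must be a superset of the network's genes")
  deg <- setNames(rep(degradation_fill, length(genes)), genes)
  deg[net$genes] <- net$degradation
  bas <- setNames(rep(0, length(genes)), genes)
  bas[net$genes] <- net$basal
  hill_network(genes, net$paths[, c("source", "target", "sign", "K", "n", "a")],
               degradation = deg, basal = bas)
}

## flat argument list handed to the C++ kernels
net_args <- function(net) {
  p <- net$paths
  list(src = match(p$source, net$genes) - 1L,
       tgt = match(p$target, net$genes) - 1L,
       act = as.integer(p$sign == "activator"),
       K = as.numeric(p$K), n = as.numeric(p$n),
       a = ifelse(is.na(p$a), 0, as.numeric(p$a)),
       deg = as.numeric(net$degradation), basal = as.numeric(net$basal))
}

#' ODE right-hand side of a network model
#'
#' For each gene i, `dx_i/dt = production_rate(paths targeting i, x) - d_i x_i`.
#' The returned function accepts a state vector or a matrix with one state per
#' row (vectorized evaluation), consistent with the flat `theta_sys` mapping
#' of [theta_sys_pack()].
#'
#' @param net A `hill_network`.
#' @return `function(x)` returning `dx/dt` with the same shape as `x`.
#' @export
network_rhs <- function(net) {
  force(net)
  function(x) {
    vec <- is.null(dim(x))
    X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
    A <- net_args(net)
    out <- net_rhs_cpp(X, A$src, A$tgt, A$act, A$K, A$n, A$a, A$deg, A$basal)
    if (vec) setNames(drop(out), net$genes) else out
  }
}

## theta_sys flattening -----------------------------------------------------
##
## Order: K of every path (by path_id), n of every path, amplitudes of the
## activator paths, degradation per gene, basal per gene.

#' Flatten the kinetic parameters of a network
#'
#' @param net A `hill_network`.
#' @return Named numeric vector: `K<id>`, `n<id>`, `a<id>`, `d_<gene>`,
#'   `b_<gene>`.
#' @export
theta_sys_pack <- function(net) {
  p <- net$paths
  ia <- p$sign == "activator"
  c(setNames(p$K, sprintf("K%02d", p$path_id)),
    setNames(p$n, sprintf("n%02d", p$path_id)),
    setNames(p$a[ia], sprintf("a%02d", p$path_id[ia])),
    setNames(as.numeric(net$degradation), paste0("d_", net$genes)),
    setNames(as.numeric(net$basal), paste0("b_", net$genes)))
}

#' Rebuild a network from a flat parameter vector
#'
#' Inverse of [theta_sys_pack()]; topology (genes, path list) is taken from
#' `net`, parameter values from `theta`.
#'
#' @param net Template `hill_network`.
#' @param theta Named vector as produced by [theta_sys_pack()].
#' @return Updated `hill_network`.
#' @export
theta_sys_unpack <- function(net, theta) {
  p <- net$paths
  ia <- p$sign == "activator"
  nm <- names(theta)
  want <- c(sprintf("K%02d", p$path_id), sprintf("n%02d", p$path_id),
            sprintf("a%02d", p$path_id[ia]),
            paste0("d_", net$genes), paste0("b_", net$genes))
  if (!identical(sort(nm), sort(want)))
    emps_error("emps_contract", "theta names do not match the network parameterization")
  p$K <- unname(theta[sprintf("K%02d", p$path_id)])
  p$n <- unname(theta[sprintf("n%02d", p$path_id)])
  p$a[ia] <- unname(theta[sprintf("a%02d", p$path_id[ia])])
  net$paths <- p
  net$degradation[] <- unname(theta[paste0("d_", net$genes)])
  net$basal[] <- unname(theta[paste0("b_", net$genes)])
  net
}

## 0-based positions of each structural parameter inside the flat vector
theta_positions <- function(net) {
  th <- theta_sys_pack(net)
  nm <- names(th)
  p <- net$paths
  ia <- p$sign == "activator"
  posA <- rep(-1L, nrow(p))
  posA[ia] <- match(sprintf("a%02d", p$path_id[ia]), nm) - 1L
  list(posK = match(sprintf("K%02d", p$path_id), nm) - 1L,
       posN = match(sprintf("n%02d", p$path_id), nm) - 1L,
       posA = posA,
       posD = match(paste0("d_", net$genes), nm) - 1L,
       posB = match(paste0("b_", net$genes), nm) - 1L,
       M = length(th), names = nm)
}

#' Box constraints on the flat kinetic-parameter vector
#'
#' All parameters are nonnegative; Hill coefficients are additionally kept in
#' `n_range` (unbounded Hill coefficients degenerate into step functions), and
#' degradation rates are kept strictly positive.
#'
#' A gene whose basal rate is exactly 0 in the model specification is treated
#' as having no constitutive production at all (mirroring how `K = 0`
#' declares the absence of a path): its basal rate is frozen at 0 rather
#' than estimated.
#'
#' @param net A `hill_network` (the *initial* model of a fit: its zero basal
#'   entries declare structure).
#' @param n_range Bounds on Hill coefficients, default `c(1, 8)`.
#' @param d_min Lower bound on degradation rates.
#' @param upper Upper bound applied to `K`, `a`, `d` and `b` (a wide box that
#'   merely keeps the optimizer finite).
#' @return `list(lower, upper)` of named vectors aligned with
#'   [theta_sys_pack()].
#' @export
theta_sys_bounds <- function(net, n_range = c(1, 8), d_min = 1e-4, upper = 1e3) {
  th <- theta_sys_pack(net)
  lo <- setNames(rep(0, length(th)), names(th))
  hi <- setNames(rep(upper, length(th)), names(th))
  isn <- grepl("^n", names(th))
  lo[isn] <- n_range[1]; hi[isn] <- n_range[2]
  lo[grepl("^d_", names(th))] <- d_min
  hi[paste0("b_", net$genes)[net$basal == 0]] <- 0
  list(lower = lo, upper = hi)
}
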
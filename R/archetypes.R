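#' Define a network partition of ICA components
#'
#' Assigns each independent component (IC) to one of the three intrinsic
#' networks analysed by the pipeline: default mode (DMN), salience (SN) and
#' executive control (ECN). The default partition places components 1--3 in
#' the DMN, 4--5 in the SN and 6--7 in the ECN.
#'
#' @param networks Character vector, one entry per component, each one of
#'   \code{"DMN"}, \code{"SN"}, \code{"ECN"}. Its length defines the number of
#'   components C.
#' @return An object of class \code{network_partition}: a list with
#'   \code{component_count} and \code{network_of} (named character vector).
#' @export
#' @examples
#' network_partition()
network_partition <- function(networks = c("DMN", "DMN", "DMN", "SN", "SN",
                                           "ECN", "ECN")) {
  networks <- as.character(networks)
  allowed <- c("DMN", "SN", "ECN")
  if (!all(networks %in% allowed)) {
    stop("network labels must be one of ", paste(allowed, collapse = ", "))
  }
  if (!all(allowed %in% networks)) {
    stop("each of DMN, SN, ECN needs at least one component")
  }
  names(networks) <- paste0("IC", seq_along(networks))
  structure(list(component_count = length(networks), network_of = networks),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("Network partition of", x$component_count, "components:\n")
  for (net in unique(x$network_of)) {
    cat("  ", net, ": ",
        paste(names(x$network_of)[x$network_of == net], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# nearest-PSD repair: clip eigenvalues at eps, then rescale to unit diagonal
repair_psd <- function(M, eps = 1e-6) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  (R + t(R)) / 2
}

#' Build the four canonical connectivity-state archetypes
#'
#' Constructs C x C correlation matrices for the four recurring connectivity
#' states typically recovered in resting-state dFNC of the DMN/SN/ECN system:
#' \describe{
#'   \item{weak}{low or neutral connectivity everywhere off the diagonal,}
#'   \item{sn_neg}{SN anti-correlated with DMN and ECN, all other blocks
#'     strongly positive,}
#'   \item{strong}{strong positive connectivity between and within all three
#'     networks,}
#'   \item{dmn_neg}{DMN anti-correlated with SN and ECN, SN--ECN and
#'     within-SN/ECN strongly positive, within-DMN weak.}
#' }
#' Each matrix is repaired to positive semi-definiteness by eigenvalue
#' clipping and re-normalised to unit diagonal.
#'
#' @param partition A \code{\link{network_partition}}.
#' @param strong_level Off-diagonal value for strongly connected blocks
#'   (default 0.6).
#' @param negative_level Off-diagonal value for anti-correlated blocks
#'   (default -0.4; must be negative).
#' @param weak_level Off-diagonal value for weak blocks (default 0.05).
#' @return Named list of four correlation matrices (names \code{weak},
#'   \code{sn_neg}, \code{strong}, \code{dmn_neg}), each with attribute
#'   \code{label}.
#' @export
#' @examples
#' arch <- build_state_archetypes(network_partition())
#' round(arch$sn_neg, 2)
build_state_archetypes <- function(partition = network_partition(),
                                   strong_level = 0.6,
                                   negative_level = -0.4,
                                   weak_level = 0.05) {
  stopifnot(inherits(partition, "network_partition"))
  if (!(weak_level >= 0 && weak_level < strong_level && strong_level <= 0.95))
    stop("require 0 <= weak_level < strong_level <= 0.95")
  if (negative_level >= 0) stop("negative_level must be < 0")

  C <- partition$component_count
  net <- partition$network_of
  in_dmn <- net == "DMN"; in_sn <- net == "SN"; in_ecn <- net == "ECN"
  cross <- function(a, b) outer(a, b, "&") | outer(b, a, "&")

  base <- function(fill) {
    M <- matrix(fill, C, C, dimnames = list(names(net), names(net)))
    diag(M) <- 1
    M
  }

  weak <- base(weak_level)

  sn_neg <- base(strong_level)
  sn_neg[cross(in_sn, in_dmn) | cross(in_sn, in_ecn)] <- negative_level
  diag(sn_neg) <- 1

  strong <- base(strong_level)

  dmn_neg <- base(strong_level)
  dmn_neg[cross(in_dmn, in_sn) | cross(in_dmn, in_ecn)] <- negative_level
  dmn_neg[outer(in_dmn, in_dmn, "&")] <- weak_level
  diag(dmn_neg) <- 1

  out <- list(weak = weak, sn_neg = sn_neg, strong = strong, dmn_neg = dmn_neg)
  out <- lapply(out, function(M) {
    R <- repair_psd(M)
    if (max(abs(R - M)) > 0.15)
      stop("requested levels are not PSD-repairable: post-repair entries ",
           "deviate from requested values by more than 0.15")
    R
  })
  for (nm in names(out)) attr(out[[nm]], "label") <- nm
  out
}
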
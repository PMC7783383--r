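# Information-theoretic comparison of partitions.

align_partitions <- function(p1, p2) {
  m1 <- if (inherits(p1, "surgcomm_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "surgcomm_partition")) p2$membership else p2
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    if (!setequal(names(m1), names(m2))) {
      stop_input("partitions are over different node sets")
    }
    m2 <- m2[names(m1)]
  } else if (length(m1) != length(m2)) {
    stop_input("partitions are over different node sets")
  }
  list(a = as.integer(factor(m1)), b = as.integer(factor(m2)))
}

# fast joint contingency table of two integer label vectors
label_crosstab <- function(a, b) {
  ka <- max(a)
  kb <- max(b)
  matrix(tabulate((a - 1L) * kb + b, nbins = ka * kb), nrow = ka, byrow = TRUE)
}

#' Variation of information between two partitions
#'
#' `VI = H(p1) + H(p2) - 2 I(p1, p2)` in nats, computed from the joint label
#' contingency table. VI is a metric on partitions: 0 iff the partitions are
#' identical, symmetric, and satisfies the triangle inequality. It is used
#' here to quantify the robustness of community structure across optimiser
#' runs and across Markov times.
#'
#' @param p1,p2 membership vectors (named by node, or in the same node
#'   order) or `surgcomm_partition` objects over the same node set.
#' @return Non-negative VI in nats.
#' @export
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 2 * ln(2)
variation_of_information <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  n <- length(al$a)
  ct <- label_crosstab(al$a, al$b)
  pij <- ct / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  pos <- pij > 0
  h_joint <- -sum(pij[pos] * log(pij[pos]))
  h_a <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  h_b <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  max(0, 2 * h_joint - h_a - h_b)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same nodes: 1
#' for identical partitions, about 0 for independent ones. Used to compare
#' detected communities against planted truth labels.
#'
#' @inheritParams variation_of_information
#' @return The ARI (a real number, at most 1).
#' @export
adjusted_rand_index <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  ct <- label_crosstab(al$a, al$b)
  n <- length(al$a)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
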
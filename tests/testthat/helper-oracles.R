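# Independent oracles used across test files.

# closed-form Gaussian similarity-index sum, written independently of
# comsiaField: value at each point p is -sum_a w_a exp(-alpha |p - x_a|^2)
fieldOracle <- function(pts, xyz, w, alpha = 0.3) {
  vapply(seq_len(nrow(pts)), function(q) {
    d2 <- colSums((t(xyz) - pts[q, ])^2)
    -sum(w * exp(-alpha * d2))
  }, numeric(1))
}

# ten hand-constructed Karva genes with their breadth-first decodings,
# worked out on paper: infix form plus the value at the stated inputs
karvaCases <- function() {
  at <- c(X0 = 1, X1 = 2, X2 = 3, X3 = 4)
  list(
    list(sym = c("+", "*", "X0", "X1", "X2"), h = 2,
         infix = "((X1*X2)+X0)", at = at, value = 7),
    list(sym = c("X1", "X0", "X0"), h = 1,
         infix = "X1", at = at, value = 2),
    list(sym = c("sin", "X0", "X1"), h = 1,
         infix = "sin(X0)", at = c(X0 = 0, X1 = 5), value = 0),
    list(sym = c("-", "/", "X2", "X0", "X1", "X2", "X2"), h = 3,
         infix = "((X0/X1)-X2)", at = c(X0 = 6, X1 = 2, X2 = 1), value = 2),
    list(sym = c("Ln", "Ln", "X0", "X1", "X2"), h = 2,
         infix = "Ln(Ln(X0))", at = c(X0 = exp(exp(1)), X1 = 0, X2 = 0),
         value = 1),
    list(sym = c("*", "+", "+", "X0", "X1", "X2", "X3"), h = 3,
         infix = "((X0+X1)*(X2+X3))", at = at, value = 21),
    list(sym = c("/", "X0", "X1", "X0", "X0"), h = 2,
         infix = "(X0/X1)", at = c(X0 = 1, X1 = 0), value = NA_real_),
    list(sym = c("sin", "+", "X0", "X1", "X2"), h = 2,
         infix = "sin((X0+X1))", at = c(X0 = pi / 2, X1 = 0, X2 = 9),
         value = 1),
    list(sym = c("+", "X0", "X1", "X2", "X3"), h = 2,
         infix = "(X0+X1)", at = at, value = 3),
    list(sym = c("+", "sin", "*", "X0", "X1", "X2", "X0"), h = 3,
         infix = "(sin(X0)+(X1*X2))", at = c(X0 = 0, X1 = 2, X2 = 3),
         value = 6)
  )
}

# tiny deterministic compound CSV written on the fly
writeTinyCompoundCSV <- function(path, ids = c("A", "B", "C"),
                                 ic50 = c(1, 2, 4),
                                 split = NULL) {
  df <- data.frame(id = ids, ic50_uM = ic50)
  if (!is.null(split)) df$split <- split
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
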
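# internal helpers shared across modules

GENOTYPES  <- c("WT", "eIF2Ad")
CONDITIONS <- c("untreated", "SM")
ASSAYS     <- c("RNA", "RPF")
UORF_CLASSES <- c("AUG", "NCC")
UORF_SOURCES <- c("annotated", "conserved", "functional")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              paste0("`", name, "` must be a finite number"))
  if (strict_min) {
    assert_that(x > min, paste0("`", name, "` must be > ", min))
  } else {
    assert_that(x >= min, paste0("`", name, "` must be >= ", min))
  }
  invisible(TRUE)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

cell_label <- function(genotype, condition) paste(genotype, condition, sep = ":")
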
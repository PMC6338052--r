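# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit(
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    }
    force(code)
}

# Deterministic ASCII ordering, independent of the session locale.
radixSort <- function(x) sort(x, method = "radix")

# Condition constructors so the CLI can map error kinds to exit codes.
apaConfigError <- function(msg) {
    stop(structure(class = c("apa_config_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

apaInputError <- function(msg) {
    stop(structure(class = c("apa_input_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

checkFileExists <- function(path, what) {
    if (!file.exists(path))
        apaInputError(sprintf("%s file not found: %s", what, path))
    invisible(path)
}

# write.table wrapper producing byte-stable TSVs.
writeTsv <- function(df, path, append = FALSE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !append, append = append)
    invisible(path)
}
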
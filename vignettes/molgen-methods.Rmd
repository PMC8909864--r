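---
title: "Generating scaffold-focused molecule libraries with molgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating scaffold-focused molecule libraries with molgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

`molgen` treats molecule generation as character-level language modelling.
A molecule is written as a SMILES string; a generative model over SMILES
characters, trained on a corpus of known molecules, implicitly learns the
syntax of the notation (ring-closure digits must pair, parentheses must
balance, valence must work out) together with the chemical regularities of
the corpus. Sampling the model character by character then proposes new
molecules. Three ideas turn this into a practical design loop:

1. **Scaffold rooting.** One molecule has many SMILES spellings, differing
   in starting atom and traversal direction. If a scaffold is spelled so
   that the string *ends* at a chosen attachment atom, autoregressive
   continuation of that string grows a substituent at exactly that
   position. Enumerating one such spelling per hydrogen-bearing atom turns
   a general generator into a positional scaffold-decoration tool.
2. **Transfer learning.** A generator trained on a large general corpus is
   fine-tuned on a small target-specific ligand set, with early layers
   frozen, yielding a target-focused generator without overfitting the
   small set from scratch.
3. **A discriminator closes the loop.** A fingerprint-based classifier
   trained on known actives/nonactives scores the generated library, so
   design candidates can be ranked before any synthesis.

## Model and training

The generator (`smiles_lm()`) is a sequential network: an LSTM layer of
`U` units, a dropout layer, a second LSTM of `U` units, and a dense softmax
over the vocabulary of size `V`. Every training string is framed as
`G s1 ... sn E` with begin/end sentinels counted in `V`; inputs are
positions `1..L-1`, targets are positions `2..L` (predict the next
character), and positions after `E` are padding excluded from the loss by a
mask. The trainable-parameter total follows the closed forms
`4(U(V+U)+U)` per LSTM (input width `V` for the first layer, `U` for the
second) and `UV+V` for the dense layer; at the reference configuration
`U = 256`, `V = 29` this totals 825,629.

Training minimises masked categorical cross-entropy with Adam
(learning rate 1e-3, default batch 512, 80/20 train/validation split).
Both the LSTM forward/backward pass (truncated nowhere: full
backpropagation through time over each padded batch) and the optimiser are
implemented in base-R matrix algebra, which is entirely adequate at the
corpus sizes the package targets and keeps every arithmetic step
inspectable. All randomness — initialisation, the split, shuffling,
dropout masks — derives from the single `seed` argument, so runs are
bit-reproducible. No early stopping is applied: the intended workflow
trains a fixed number of epochs, checkpoints every epoch, and picks
checkpoints by inspecting the history, which is why `checkpoint_dir` /
`keep_epochs` and `load_checkpoint()` exist.

Two per-epoch diagnostics supplement loss and next-token accuracy:
`log_loss` (validation cross-entropy in nats; `log(V)` for a uniform
predictor) and a `wasserstein` diagnostic, the 1-D Wasserstein distance
between the character-frequency distribution of a small seeded sample and
that of the validation corpus, with characters ordered by vocabulary
index. The Wasserstein quantity is deliberately modest: it tracks whether
sampled *character statistics* approach the corpus, not structural
similarity, and is labelled a diagnostic rather than a headline metric.

## Sampling and temperature

`sample_smiles()` draws characters from the temperature-reshaped
predictive distribution `q_i = p_i^{1/T} / sum_j p_j^{1/T}` until `E` or a
length cap (`max_len = 140` characters by default — a convention chosen to
be far above any reasonable drug-like SMILES length, not a tuned value).
The transform is monotone, so it never changes which character is most
likely; `T < 1` concentrates mass on the mode, `T > 1` flattens. Strings
that hit the cap without `E` are returned flagged and counted as invalid
downstream. Sampling campaigns (`run_campaign()`) iterate checkpoints x
temperatures x attachment sites; each cell derives its own sub-seed by
hashing the campaign coordinates, so any cell is reproducible in isolation.

## Rooted scaffold spellings

`rooted_library()` enumerates attachment sites (every heavy atom with at
least one hydrogen, no symmetry reduction — chemically equivalent sites are
deliberately kept, as position bookkeeping, not uniqueness, is the goal)
and searches for a spelling per site: canonical traversals rooted at each
atom, then random traversals, then a deterministic "branch-wrapped"
construction for cut-vertex atoms that no linear traversal can terminate
at (the spelling is rooted *at* the site with every substituent in
parentheses, so an appended token still bonds to the site). Kekulé
spellings are used throughout so that appending to an aromatic N-H needs
no bracket-hydrogen rewriting. Correctness is defined by verification, not
construction: a candidate is accepted only if (a) it canonicalises to the
scaffold itself and (b) the candidate with `"C"` appended canonicalises to
the scaffold carrying one methyl at the designated atom, where the
reference is built by an independent graph edit. This methyl-append test
is the module's contract and is what the test suite asserts.

## Transfer learning

`finetune()` continues training on a target corpus under a freezing
strategy: `first_lstm` (default; the first LSTM's parameters are kept
constant while the second LSTM and dense layer adapt), `both_lstm`, or
`none`. Freezing is exact — frozen tensors are bit-identical before and
after — and the trainable budget drops by the frozen layers' closed forms.
Characters in the target corpus that are missing from the base vocabulary
are a hard error: silently growing the vocabulary would invalidate the
one-hot input layer. The Adam state is instantiated fresh for fine-tuning;
no optimiser state is carried over. `compare_strategies()` runs a small
grid (strategy x batch size) and returns the loss/accuracy curves without
imposing a ranking.

## Library metrics

`library_metrics()` reports the chain validity = n_valid/n_sampled
(parse + sanitize), uniqueness = n_unique/n_valid, novelty =
n_novel/n_unique, so `n_novel <= n_unique <= n_valid <= n_sampled` holds by
construction. Uniqueness deduplicates by canonical structure (the stricter
and chemically meaningful reading; raw-string mode is available via
`dedup = "string"`). Novelty uses 166-bit MACCS keys with the Tanimoto
coefficient — the field's conventional similarity choice, recorded in the
output metadata — and a strict `< 0.85` threshold; the reference collection
is an explicit argument. Descriptors (MW, Ertl TPSA, Crippen SMR/SlogP),
the Ertl-Schuffenhauer synthetic-accessibility score and the QED
drug-likeness index are computed by their published reference
implementations in RDKit, reached through the bundled Python helper; they
are standard published algorithms and are intentionally not re-derived.
`embed_2d()` standardises a feature table and embeds it with exact-method
t-SNE so fixed seeds give identical coordinates.

## Discriminator

`label_by_ki()` splits activity records at a Ki cutoff of 100 nM, strict:
a boundary Ki equal to the cutoff is inactive. `assemble_training_set()`
fingerprints actives, inactives and decoys (decoys are always nonactive).
The classifier (`maccs_mlp()`) is a perceptron with three densely
connected ReLU hidden layers of 166 units on the 166-bit input, sigmoid
output, Adam on binary cross-entropy; 0.5 is the decision threshold for
confusion-matrix metrics (a plain convention, exposed in code).
`cross_validate()` performs stratified k-fold CV (default k = 6;
stratification avoids empty-class folds under the heavy decoy imbalance
this design produces), reports precision, recall, F1, accuracy, Cohen's
kappa and MCC per fold, pools held-out scores for the ROC curve, and
computes AUC by mid-rank Mann-Whitney. Ratios with zero denominators are
reported as 0 and flagged, because degenerate folds are a real possibility
at small n with few actives. No class re-weighting is applied; the
imbalance is simply reported.

## What the synthetic fixtures emulate — and what they do not

The package ships seeded generators instead of external data.
`toy_smiles_corpus()` assembles molecules from valid-by-construction
grammar rules — single-bonded chains, one optional branch or C=C double
bond, one optional 5/6-ring with closure digit 1 or 2 — over a C/N/O
alphabet with carbon-weighted draws (70/15/15) and 6-14 heavy atoms.
These choices are deliberate stand-ins for salient properties of a real
training collection:

* *validity 1.0 by construction* (so validity of a generated set measures
  the model, not the fixture);
* *carbon-dominated character statistics*, as in organic drug-like
  molecules — this skew is also what gives sampling temperature its
  leverage, since temperature reshaping is a no-op on a uniform
  distribution;
* *fragment-to-lead molecule sizes*, keeping the space of valid molecules
  large relative to typical sampling depths.

They do **not** emulate realistic property or ring-system distributions,
aromaticity, stereochemistry, charged species or multi-character element
tokens. Passing the qualitative property tests (validity falling and
uniqueness rising with temperature; motif enrichment after fine-tuning)
therefore demonstrates that the machinery behaves as the underlying theory
predicts on corpora with these statistics, not that any particular
screening-library-scale result is reproduced.

`motif_enriched_corpus()` emulates a small target-ligand set in which a
privileged scaffold (default: an indole, supplied as an append-ready
rooted spelling) recurs at a requested enrichment, with short appended
substituent chains. `separable_fingerprint_dataset()` builds a two-class
166-bit set from maximally separated templates with independent bit flips;
at flip rate 0.05 the expected within-class Hamming distance to the
template is 166 x 0.05 = 8.3 bits and the classes are comfortably
separable, giving the discriminator an unambiguous test bed.

## Desk-scale reference configuration

The test suite and examples use one fixed configuration, chosen once as a
realistic desk-scale rendition of the full study design: 2,000 corpus
molecules, 64 LSTM units, 30 training epochs, batch 128 (the small-corpus
batch size; with only a few thousand strings the default 512 yields too
few gradient updates per epoch to converge in 30 epochs), seed 7. The
transfer stage fine-tunes on a 950-molecule motif-enriched corpus for 40
epochs at batch 128 — 40 epochs being the standard fine-tuning depth for
this architecture; shorter fine-tuning (20 epochs) moves the character
statistics towards the target corpus but does not yet reproduce the full
20-character motif spelling, so enrichment only becomes measurable at the
full depth. The capacity-comparison property (a wider net overfits a small
corpus more) is run at 96 vs 16 units on 150 molecules rather than
512 vs 256 on thousands, which exercises the same phenomenon at a fraction
of the cost.

Numerical conventions: probabilities are clamped at 1e-12 before logs;
temperature reshaping is computed in log space; LSTM forget-gate biases
start at 1; weights are Glorot-uniform from the seeded RNG; the
end-of-string sentinel terminates decoding, and anything sampled after a
stray `E` is discarded.

## Known limitations

* Tokenisation is raw single characters. Two-character element symbols
  ("Cl", "Br") are two tokens; the toy alphabet avoids them entirely.
* The chemistry backend requires a system `python` with RDKit; each call
  spawns a short-lived process, so the package batches chemistry calls and
  so should callers.
* The base-R LSTM is single-threaded-CPU fast for corpora up to tens of
  thousands of strings; it is not intended for half-million-molecule,
  100-epoch replications, although nothing in the interface forbids them.
* The Wasserstein diagnostic is a character-level summary only.

## A worked end-to-end loop

```{r}
library(molgen)

corpus <- toy_smiles_corpus(2000, seed = 7)
model <- smiles_lm(corpus, units = 64, epochs = 30, batch_size = 128,
                   seed = 7)

rooted <- rooted_library("C12=C(C=CC=C2)NC=C1")   # 7 indole positions
target <- motif_enriched_corpus(950, seed = 11, enrichment = 1)
tmodel <- finetune(model, target, freeze = "first_lstm", epochs = 40,
                   batch_size = 128, seed = 13)

samples <- run_campaign(list(t40 = tmodel), rooted,
                        temperatures = c(0.5, 1.0, 1.2, 1.5),
                        n_samples = 250, seed = 11)
library_metrics(samples, reference = target)

ds <- separable_fingerprint_dataset(300, 300, flip_rate = 0.05, seed = 3)
cross_validate(ds, k = 6, seed = 3, epochs = 30)
```
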
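#include <Rcpp.h>
using namespace Rcpp;

// One synchronous update of all community cells' secreter and reservoir
// genes. `state` is the C x N gene matrix at time t, `sensed` the C x (1+E)
// matrix of already-updated input-gene and receptor values for t+1 (so
// regulators with index <= E+1 contribute their new value, all others their
// old one). `strains` holds, per strain, the 0-based regulator lists and
// truth tables of genes E+2..N in order; the first-listed regulator is the
// least significant truth-table index bit.
// [[Rcpp::export]]
IntegerMatrix rbn_step_cpp(const IntegerMatrix& state,
                           const IntegerMatrix& sensed,
                           const IntegerVector& strain_id,
                           const List& strains) {
  const int C = state.nrow(), N = state.ncol();
  const int E1 = sensed.ncol();  // 1 + E
  IntegerMatrix out(C, N);

  const int S = strains.size();
  std::vector<std::vector<IntegerVector>> inputs(S), tables(S);
  for (int s = 0; s < S; ++s) {
    List st = strains[s];
    List inp = st["inputs"], tab = st["tables"];
    const int ng = inp.size();
    inputs[s].reserve(ng);
    tables[s].reserve(ng);
    for (int g = 0; g < ng; ++g) {
      inputs[s].push_back(inp[g]);
      tables[s].push_back(tab[g]);
    }
    if (ng != N - E1) stop("strain gene count does not match state layout");
  }

  for (int c = 0; c < C; ++c) {
    const int s = strain_id[c] - 1;
    if (s < 0 || s >= S) stop("strain id out of range");
    for (int j = 0; j < E1; ++j) out(c, j) = sensed(c, j);
    const int ng = inputs[s].size();
    for (int g = 0; g < ng; ++g) {
      const IntegerVector& in = inputs[s][g];
      int idx = 0;
      for (int j = 0; j < in.size(); ++j) {
        const int gi = in[j];  // 0-based gene index
        if (gi < 0 || gi >= N) stop("regulator index out of range");
        const int v = (gi < E1) ? out(c, gi) : state(c, gi);
        idx |= (v << j);
      }
      out(c, E1 + g) = tables[s][g][idx];
    }
  }
  return out;
}
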
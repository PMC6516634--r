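#include <Rcpp.h>
#include <cmath>
#include <string>

using namespace Rcpp;

// Nearest-neighbor duplex melting temperature, unified thermodynamic
// parameter set (SantaLucia 1998), Owczarzy-style monovalent-salt entropy
// correction (0.368 * (N-1) * ln[Na+]) and a linear formamide correction
// of 0.65 degC per percent.

static inline int base_idx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// dH (kcal/mol), dS (cal/mol/K) indexed by 4*first+second
static const double NN_DH[16] = {
    /*AA*/ -7.9, /*AC*/ -8.4, /*AG*/ -7.8, /*AT*/ -7.2,
    /*CA*/ -8.5, /*CC*/ -8.0, /*CG*/ -10.6, /*CT*/ -7.8,
    /*GA*/ -8.2, /*GC*/ -9.8, /*GG*/ -8.0, /*GT*/ -8.4,
    /*TA*/ -7.2, /*TC*/ -8.2, /*TG*/ -8.5, /*TT*/ -7.9
};
static const double NN_DS[16] = {
    /*AA*/ -22.2, /*AC*/ -22.4, /*AG*/ -21.0, /*AT*/ -20.4,
    /*CA*/ -22.7, /*CC*/ -19.9, /*CG*/ -27.2, /*CT*/ -21.0,
    /*GA*/ -22.2, /*GC*/ -24.4, /*GG*/ -19.9, /*GT*/ -22.4,
    /*TA*/ -21.3, /*TC*/ -22.2, /*TG*/ -22.7, /*TT*/ -22.2
};

static bool self_complementary(const std::string &s) {
    const size_t n = s.size();
    static const char comp[4] = {'T', 'G', 'C', 'A'};
    for (size_t i = 0; i < n; ++i) {
        int b = base_idx(s[n - 1 - i]);
        if (b < 0 || s[i] != comp[b]) return false;
    }
    return true;
}

// [[Rcpp::export]]
NumericVector tm_nn_cpp(CharacterVector seqs, double dnac1_nM, double dnac2_nM,
                        double na_mM, double fmd_pct) {
    const double R = 1.987; // cal/(mol K)
    NumericVector out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        const int n = (int)s.size();
        if (n < 2) { out[i] = NA_REAL; continue; }
        double dh = 0.0, ds = 0.0;
        bool ok = true;
        // terminal initiation terms
        for (int e = 0; e < 2; ++e) {
            char c = e == 0 ? s[0] : s[n - 1];
            int b = base_idx(c);
            if (b < 0) { ok = false; break; }
            if (c == 'A' || c == 'T') { dh += 2.3; ds += 4.1; }
            else { dh += 0.1; ds += -2.8; }
        }
        if (!ok) { out[i] = NA_REAL; continue; }
        for (int j = 0; j + 1 < n; ++j) {
            int a = base_idx(s[j]), b = base_idx(s[j + 1]);
            if (a < 0 || b < 0) { ok = false; break; }
            dh += NN_DH[4 * a + b];
            ds += NN_DS[4 * a + b];
        }
        if (!ok) { out[i] = NA_REAL; continue; }
        double conc;
        if (self_complementary(s)) {
            ds += -1.4;
            conc = dnac1_nM * 1e-9;
        } else {
            conc = (dnac1_nM - dnac2_nM / 2.0) * 1e-9;
        }
        ds += 0.368 * (n - 1) * std::log(na_mM / 1000.0);
        double tm = (1000.0 * dh) / (ds + R * std::log(conc)) - 273.15;
        tm -= 0.65 * fmd_pct;
        out[i] = tm;
    }
    return out;
}
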
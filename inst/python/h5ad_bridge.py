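"""Convert between AnnData .h5ad files and a plain MTX directory.

Directory layout (shared with the R loader):
  matrix.mtx   genes x spots counts
  barcodes.tsv one barcode per line
  features.tsv gene id / name / type, tab-separated, no header
  coords.csv   barcode,x,y[,in_tissue]
  labels.csv   barcode,domain (optional)
"""
import sys


def export(h5ad_path, outdir):
    import os
    import anndata
    import numpy as np
    import pandas as pd
    import scipy.io as sio
    import scipy.sparse as sp

    ad = anndata.read_h5ad(h5ad_path)
    os.makedirs(outdir, exist_ok=True)
    X = ad.X
    if not sp.issparse(X):
        X = sp.csr_matrix(np.asarray(X))
    sio.mmwrite(os.path.join(outdir, "matrix.mtx"), X.T.tocoo())
    with open(os.path.join(outdir, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, ad.obs_names)) + "\n")
    pd.DataFrame({
        "id": ad.var_names, "name": ad.var_names, "type": "Gene Expression",
    }).to_csv(os.path.join(outdir, "features.tsv"), sep="\t",
              header=False, index=False)
    if "spatial" in ad.obsm:
        xy = np.asarray(ad.obsm["spatial"])
    else:
        raise SystemExit("h5ad has no obsm['spatial'] coordinates")
    coords = pd.DataFrame({"barcode": ad.obs_names, "x": xy[:, 0], "y": xy[:, 1]})
    if "in_tissue" in ad.obs:
        coords["in_tissue"] = np.asarray(ad.obs["in_tissue"]).astype(int)
    coords.to_csv(os.path.join(outdir, "coords.csv"), index=False)
    if "domain" in ad.obs:
        pd.DataFrame({"barcode": ad.obs_names,
                      "domain": np.asarray(ad.obs["domain"])}).to_csv(
            os.path.join(outdir, "labels.csv"), index=False)


def import_(indir, h5ad_path):
    import os
    import anndata
    import numpy as np
    import pandas as pd
    import scipy.io as sio

    X = sio.mmread(os.path.join(indir, "matrix.mtx")).T.tocsr()
    barcodes = [l.strip() for l in open(os.path.join(indir, "barcodes.tsv")) if l.strip()]
    feats = pd.read_csv(os.path.join(indir, "features.tsv"), sep="\t", header=None)
    coords = pd.read_csv(os.path.join(indir, "coords.csv"))
    coords = coords.set_index("barcode").loc[barcodes]
    ad = anndata.AnnData(X=X)
    ad.obs_names = barcodes
    ad.var_names = feats[0].astype(str).tolist()
    ad.obsm["spatial"] = coords[["x", "y"]].to_numpy()
    if "in_tissue" in coords:
        ad.obs["in_tissue"] = coords["in_tissue"].to_numpy().astype(bool)
    lab_path = os.path.join(indir, "labels.csv")
    if os.path.exists(lab_path):
        lab = pd.read_csv(lab_path).set_index("barcode").loc[barcodes]
        ad.obs["domain"] = lab["domain"].to_numpy()
    ad.write_h5ad(h5ad_path)


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in {"export", "import"}:
        raise SystemExit("usage: h5ad_bridge.py export <in.h5ad> <outdir> | "
                         "import <indir> <out.h5ad>")
    if sys.argv[1] == "export":
        export(sys.argv[2], sys.argv[3])
    else:
        import_(sys.argv[2], sys.argv[3])
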
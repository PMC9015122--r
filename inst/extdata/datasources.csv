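datasource,prefix
Ensembl,ensembl
Entrez Gene,ncbigene
NCBI Gene,ncbigene
HGNC,hgnc.symbol
UniProtKB,uniprot
Uniprot-TrEMBL,uniprot
HMDB,hmdb
ChEBI,chebi
PubChem-compound,pubchem.compound
KEGG Compound,kegg.compound
Wikidata,wikidata
WikiPathways,wikipathways
Rhea,rhea
Reactome,reactome
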
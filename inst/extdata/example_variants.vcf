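##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CONSEQ,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar significance">
##INFO=<ID=GAC,Number=1,Type=Integer,Description="gnomAD allele count">
##INFO=<ID=GAF,Number=1,Type=Float,Description="gnomAD allele frequency">
##INFO=<ID=GHOM,Number=1,Type=Integer,Description="gnomAD homozygote count">
##INFO=<ID=PROVEAN,Number=1,Type=Float,Description="PROVEAN score">
##INFO=<ID=SQUIRLS,Number=1,Type=Float,Description="SQUIRLS score">
##INFO=<ID=SPLICEAI,Number=1,Type=Float,Description="SpliceAI delta score">
##INFO=<ID=ADA,Number=1,Type=Float,Description="dbscSNV ADA score">
##INFO=<ID=RF,Number=1,Type=Float,Description="dbscSNV RF score">
##INFO=<ID=PREDCALLS,Number=1,Type=String,Description="Predictor calls">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01
chr1	1001200	.	G	A	120	PASS	GENE=GENE0001;CONSEQ=missense;CLNSIG=absent;GAC=2;GAF=0.000008;GHOM=0;PREDCALLS=D|D|D|T|.|D|D|T|D|D	GT:DP:AD	0/1:100:50,50
chr2	2002400	.	C	T	90	PASS	GENE=GENE0002;CONSEQ=stop_gain;CLNSIG=pathogenic	GT:DP:AD	1/1:60:3,57
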
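qualifier	route	target
allele	annotation	local:allele
anticodon	annotation	local:anticodon
bio_material	collection	bioMaterial
bound_moiety	annotation	local:bound_moiety
breed	collection	breed
cell_line	collection	cellLine
cell_type	collection	cellType
chloroplast	annotation	local:chloroplast
chromoplast	annotation	local:chromoplast
chromosome	annotation	local:chromosome
citation	annotation	local:citation
clone	collection	clone
clone_lib	collection	cloneLib
codon	annotation	local:codon
codon_start	annotation	local:codon_start
collected_by	collection	collectedBy
collection_date	collection	collectionDate
compare	annotation	local:compare
cons_splice	annotation	local:cons_splice
country	collection	country
cultivar	collection	cultivar
culture_collection	collection	cultureCollection
cyanelle	annotation	local:cyanelle
db_xref	taxonomy	ncbiTaxonId
dev_stage	collection	devStage
direction	annotation	local:direction
EC_number	annotation	local:EC_number
ecotype	collection	ecotype
environmental_sample	collection	environmentalSample
estimated_length	annotation	local:estimated_length
evidence	annotation	local:evidence
exception	annotation	local:exception
experiment	annotation	local:experiment
focus	annotation	local:focus
frequency	annotation	local:frequency
function	annotation	local:function
gene	annotation	local:gene
germline	annotation	local:germline
haplotype	collection	haplotype
identified_by	collection	identifiedBy
inference	annotation	local:inference
insertion_seq	annotation	local:insertion_seq
isolate	collection	isolate
isolation_source	collection	isolationSource
kinetoplast	annotation	local:kinetoplast
lab_host	collection	labHost
label	annotation	local:label
lat_lon	collection	latLon
locus_tag	annotation	local:locus_tag
macronuclear	annotation	local:macronuclear
map	annotation	local:map
mitochondrion	annotation	local:mitochondrion
mod_base	annotation	local:mod_base
mol_type	annotation	local:mol_type
note	annotation	local:note
number	annotation	local:number
old_locus_tag	annotation	local:old_locus_tag
operon	annotation	local:operon
organelle	annotation	local:organelle
organism	taxonomy	organismName
partial	annotation	local:partial
PCR_conditions	annotation	local:PCR_conditions
phenotype	annotation	local:phenotype
plasmid	annotation	local:plasmid
pop_variant	collection	popVariant
product	annotation	local:product
protein_id	annotation	local:protein_id
proviral	annotation	local:proviral
pseudo	annotation	local:pseudo
rearranged	annotation	local:rearranged
replace	annotation	local:replace
rpt_family	annotation	local:rpt_family
rpt_type	annotation	local:rpt_type
rpt_unit	annotation	local:rpt_unit
segment	annotation	local:segment
sequenced_mol	annotation	local:sequenced_mol
serotype	collection	serotype
serovar	collection	serovar
sex	collection	sex
specific_host	collection	specificHost
specimen_voucher	collection	specimenVoucher
standard_name	annotation	local:standard_name
strain	collection	strain
sub_clone	collection	subClone
sub_species	collection	subSpecies
sub_strain	collection	subStrain
tissue_lib	collection	tissueLib
tissue_type	collection	tissueType
transgenic	annotation	local:transgenic
transl_except	annotation	local:transl_except
transl_table	annotation	local:transl_table
translation	suppressed	-
transposon	annotation	local:transposon
usedin	annotation	local:usedin
variety	collection	variety
virion	annotation	local:virion
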
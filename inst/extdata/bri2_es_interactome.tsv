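accession	gene_symbol	protein_name	regions
P13233	Cnp	2′,3′-cyclic-nucleotide 3′-phosphodiesterase	CC, HP, CB
P23565	Ina	Alpha-internexin	CC, HP, CB
O08838	Amph	Amphiphysin	CC, HP, CB
P0C6S7	Anks1b	Ankyrin repeat and sterile alpha motif domain-containing protein 1B	CC
Q8CGU4	Agap2	Arf-GAP with GTPase, ANK repeat and PH domain-containing protein 2	CC
Q6PST4	Atl1	Atlastin-1	CC
Q05764	Add2	Beta-adducin	HP
P85969	Napb	Beta-soluble NSF attachment protein	HP
Q05175	Basp1	Brain acid soluble protein 1	HP
P55068	Bcan	Brevican core protein	HP, CB
P11275	Camk2a	Calcium/calmodulin-dependent protein kinase type II subunit alpha	CC, HP
P08413	Camk2b	Calcium/calmodulin-dependent protein kinase type II subunit beta	CC, HP, CB
Q62717	Cadps	Calcium-dependent secretion activator 1	HP
Q63092	Camkv	CaM kinase-like vesicle-associated protein	HP
Q1WIM1	Cadm4	Cell adhesion molecule 4	CB
Q5FVI4	Cend1	Cell cycle exit and neuronal differentiation protein 1	CC, HP
Q05140	Snap91	Clathrin coat assembly protein AP180	CC, HP
P63041	Cplx1	Complexin-1	HP
Q9Z1T4	Cnksr2	Connector enhancer of kinase suppressor of ras 2	CC
Q63198	Cntn1	Contactin-1	CC, HP
P97846	Cntnap1	Contactin-associated protein 1	CC, CB
Q5BJS7	Cpne9	Copine-9	HP
Q62950	Crmp1	Dihydropyrimidinase-related protein 1	HP
Q62951	Dpysl4	Dihydropyrimidinase-related protein 4	CB
Q63622	Dlg2	Disks large homolog 2	CC
P31016	Dlg4	Disks large homolog 4	CC, HP, CB
P97836	Dlgap1	Disks large-associated protein 1	CC
P97837	Dlgap2	Disks large-associated protein 2	CC
P97838	Dlgap3	Disks large-associated protein 3	CC
P21575	Dnm1	Dynamin-1	CC, HP
Q8R491	Ehd3	EH domain-containing protein 3	HP
Q8CH84	Elavl2	ELAV-like protein 2	CC
O35179	Sh3gl2	Endophilin-A1	CC, CB
P24942	Slc1a3	Excitatory amino acid transporter 1	CC, HP, CB
P31596	Slc1a2	Excitatory amino acid transporter 2	CC, HP, CB
O35921	Slc1a6	Excitatory amino acid transporter 4	CB
O88871	Gabbr2	Gamma-aminobutyric acid type B receptor subunit 2	CC
P47819	Gfap	Glial fibrillary acidic protein	CC, HP, CB
P19490	Gria1	Glutamate receptor 1	CC
P19491	Gria2	Glutamate receptor 2	CC, HP, CB
P35439	Grin1	Glutamate receptor ionotropic, NMDA 1	CC
Q00960	Grin2b	Glutamate receptor ionotropic, NMDA 2B	CC
Q9WTT6	Gda	Guanine deaminase	CC
P19627	Gnaz	Guanine nucleotide-binding protein G	CC, HP
P59215	Gnao1	Guanine nucleotide-binding protein G	CC, HP, CB
Q9Z214	Homer1	Homer protein homolog 1	CC
Q9ESM2	Hapln2	Hyaluronan and proteoglycan link protein 2	CC, CB
Q9QYU4	Crym	Ketimine reductase mu-crystallin	HP
Q6QLM7	Kif5a	Kinesin heavy chain isoform 5 A	CC, HP, CB
P56536	Kif5c	Kinesin heavy chain isoform 5 C	CC, CB
P37285	Klc1	Kinesin light chain 1	CC, HP, CB
Q62813	Lsamp	Limbic system-associated membrane protein	CC, CB
P34926	Map1a	Microtubule-associated protein 1 A	CC, HP
P15205	Map1b	Microtubule-associated protein 1B	CC, HP, CB
P15146	Map2	Microtubule-associated protein 2	CC
Q63560	Map6	Microtubule-associated protein 6	CC, HP, CB
Q505J6	Slc25a18	Mitochondrial glutamate carrier 2	CC
P02688	Mbp	Myelin basic protein	CC
P60203	Plp1	Myelin proteolipid protein	CC, CB
P07722	Mag	Myelin-associated glycoprotein	CC, CB
Q63345	Mog	Myelin-oligodendrocyte glycoprotein	CC, CB
P13596	Ncam1	Neural cell adhesion molecule 1	CB
P55067	Ncan	Neurocan core protein	CC, HP, CB
O35095	Ncdn	Neurochondrin	CC
P19527	Nefl	Neurofilament light polypeptide	CC, HP, CB
P12839	Nefm	Neurofilament medium polypeptide	CC, CB
P07936	Gap43	Neuromodulin	CC
Q9ESI7	Dcx	Neuronal migration protein doublecortin	CC
Q9WU34	Sept3	Neuronal-specific septin-3	HP
Q62718	Ntm	Neurotrimin	CC, CB
P11506	Atp2b2	Plasma membrane calcium-transporting ATPase 2	CC
Q64568	Atp2b3	Plasma membrane calcium-transporting ATPase 3	HP
P10499	Kcna1	Potassium voltage-gated channel subfamily A member 1	CC
Q6MG82	Prrt1	Proline-rich transmembrane protein 1	HP
O88778	Bsn	Protein bassoon	CC, CB
P63319	Prkcg	Protein kinase C gamma type	CC, HP, CB
Q9JKS6	Pclo	Protein piccolo	CC
P47709	Rph3a	Rabphilin-3A	CC, HP
P63012	Rab3a	Ras-related protein Rab-3A	CC, HP, CB
P62824	Rab3c	Ras-related protein Rab-3C	CC, HP
Q9JIR4	Rims1	Regulating synaptic membrane exocytosis protein 1	CC
Q64548	Rtn1	Reticulon-1	CC, HP, CB
Q9JKE3	Scamp5	Secretory carrier-associated membrane protein 5	CC, HP
Q9JJM9	Sept5	Septin-5	CC, HP
O08875	Dclk1	Serine/threonine-protein kinase DCLK1	CC, HP
Q9WV48	Shank1	SH3 and multiple ankyrin repeat domains protein 1	CC, CB
P0DJJ3	Sgip1	SH3-containing GRB2-like protein 3-interacting protein 1	CC, HP
P31647	Slc6a11	Sodium- and chloride-dependent GABA transporter 3	CC, CB
P48768	Slc8a2	Sodium/calcium exchanger 2	CC
P06686	Atp1a2	Sodium/potassium-transporting ATPase subunit alpha-2	CC
P06687	Atp1a3	Sodium/potassium-transporting ATPase subunit alpha-3	CC, HP
P13638	Atp1b2	Sodium/potassium-transporting ATPase subunit beta-2	CC, HP, CB
Q63633	Slc12a5	Solute carrier family 12 member 5	HP
Q9QWN8	Sptbn2	Spectrin beta chain, non-erythrocytic 2	CC, CB
Q9QXY2	Srcin1	SRC kinase signaling inhibitor 1	CC, CB
P09951	Syn1	Synapsin-1	CC, HP
Q63537	Syn2	Synapsin-2	CC
Q02563	Sv2a	Synaptic vesicle glycoprotein 2 A	CC, HP, CB
Q63564	Sv2b	Synaptic vesicle glycoprotein 2B	CC, HP
P07825	Syp	Synaptophysin	CC, HP
P60881	Snap25	Synaptosomal-associated protein 25	HP, CB
P21707	Syt1	Synaptotagmin-1	CC, HP, CB
P97610	Syt12	Synaptotagmin-12	CC, CB
P29101	Syt2	Synaptotagmin-2	CB
Q62747	Syt7	Synaptotagmin-7	CB
P32851	Stx1a	Syntaxin-1A	CC
P61265	Stx1b	Syntaxin-1B	CC, HP, CB
P61765	Stxbp1	Syntaxin-binding protein 1	CC, HP
Q05546	Tnr	Tenascin-R	CC, HP, CB
P70566	Tmod2	Tropomodulin-2	CC, CB
P85108	Tubb2a	Tubulin beta-2A chain	CC, HP, CB
Q3KRE8	Tubb2b	Tubulin beta-2B chain	CC, HP
Q4QRB4	Tubb3	Tubulin beta-3 chain	CC, HP, CB
Q9QUL6	Nsf	Vesicle-fusing ATPase	CC, HP, CB
Q62634	Slc17a7	Vesicular glutamate transporter 1	CC, HP
Q9JI12	Slc17a6	Vesicular glutamate transporter 2	CC
O35458	Slc32a1	Vesicular inhibitory amino acid transporter	CC, HP
P62762	Vsnl1	Visinin-like protein 1	CB
Q71RJ2	Cacng2	Voltage-dependent calcium channel gamma-2 subunit	CB
Q6QIX3	Slc30a3	Zinc transporter 3	CC
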
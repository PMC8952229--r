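term_id	term_label	category_hint
GO:0005515	protein binding	go-molecular-function
GO:0005524	ATP binding	go-molecular-function
GO:0003677	DNA binding	go-molecular-function
GO:0003700	DNA-binding transcription factor activity	go-molecular-function
GO:0000981	DNA-binding transcription factor activity, RNA polymerase II-specific	go-molecular-function
GO:0003823	antigen binding	go-molecular-function
GO:0034987	immunoglobulin receptor binding	go-molecular-function
GO:0004674	protein serine/threonine kinase activity	go-molecular-function
GO:0003723	RNA binding	go-molecular-function
GO:0008270	zinc ion binding	go-molecular-function
GO:0046872	metal ion binding	go-molecular-function
GO:0042802	identical protein binding	go-molecular-function
GO:0044877	protein-containing complex binding	go-molecular-function
GO:0002377	immunoglobulin production	go-biological-process
GO:0006910	phagocytosis, recognition	go-biological-process
GO:0006911	phagocytosis, engulfment	go-biological-process
GO:0050871	positive regulation of B cell activation	go-biological-process
GO:0006958	complement activation, classical pathway	go-biological-process
GO:0050853	B cell receptor signaling pathway	go-biological-process
GO:0006955	immune response	go-biological-process
GO:0042742	defense response to bacterium	go-biological-process
GO:0002250	adaptive immune response	go-biological-process
GO:0006355	regulation of transcription, DNA-templated	go-biological-process
GO:0006357	regulation of transcription by RNA polymerase II	go-biological-process
GO:0045893	positive regulation of transcription, DNA-templated	go-biological-process
GO:0045944	positive regulation of transcription by RNA polymerase II	go-biological-process
GO:0055114	oxidation-reduction process	go-biological-process
GO:0007165	signal transduction	go-biological-process
GO:0006915	apoptotic process	go-biological-process
GO:0016055	Wnt signaling pathway	pathway
GO:0007186	G protein-coupled receptor signaling pathway	pathway
GO:0042981	regulation of apoptotic process	pathway
GO:0000165	MAPK cascade	pathway
GO:0038095	Fc-epsilon receptor signaling pathway	pathway
GO:0004672	protein kinase activity	catalytic-activity
GO:0016787	hydrolase activity	catalytic-activity
GO:0016740	transferase activity	catalytic-activity
GO:0004842	ubiquitin-protein transferase activity	catalytic-activity
GO:0022857	transmembrane transporter activity	transport-activity
GO:0005216	ion channel activity	transport-activity
GO:0015075	ion transmembrane transporter activity	transport-activity
GO:0005342	organic acid transmembrane transporter activity	transport-activity
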
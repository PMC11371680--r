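pt	soc	meddra_version
Hypoxia	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Respiratory failure	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Acute respiratory failure	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Tachypnoea	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Pleural effusion	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Pulmonary oedema	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Acute respiratory distress syndrome	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Pulmonary haemorrhage	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Atelectasis	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Lung opacity	Respiratory, thoracic and mediastinal disorders	0.0-synthetic-demo
Pyrexia	General disorders and administration site conditions	0.0-synthetic-demo
Fatigue	General disorders and administration site conditions	0.0-synthetic-demo
Oedema peripheral	General disorders and administration site conditions	0.0-synthetic-demo
Nausea	Gastrointestinal disorders	0.0-synthetic-demo
Vomiting	Gastrointestinal disorders	0.0-synthetic-demo
Diarrhoea	Gastrointestinal disorders	0.0-synthetic-demo
Headache	Nervous system disorders	0.0-synthetic-demo
Tremor	Nervous system disorders	0.0-synthetic-demo
Confusional state	Psychiatric disorders	0.0-synthetic-demo
Cytokine release syndrome	Immune system disorders	0.0-synthetic-demo
Hypotension	Vascular disorders	0.0-synthetic-demo
Anaemia	Blood and lymphatic system disorders	0.0-synthetic-demo
Neutropenia	Blood and lymphatic system disorders	0.0-synthetic-demo
Rash	Skin and subcutaneous tissue disorders	0.0-synthetic-demo
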
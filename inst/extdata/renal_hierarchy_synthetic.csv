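soc,hlgt,hlt,pt,llt
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Acute kidney injury,Acute renal failure
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Acute kidney injury,Kidney injury acute
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Renal failure,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Renal impairment,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Prerenal failure,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Chronic kidney disease,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Anuria,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal failure and impairment,Oliguria,
Renal and urinary disorders,Nephropathies,glomerulonephritis and nephrotic syndrome,Nephrotic syndrome,
Renal and urinary disorders,Nephropathies,glomerulonephritis and nephrotic syndrome,Glomerulonephritis,
Renal and urinary disorders,Nephropathies,glomerulonephritis and nephrotic syndrome,Glomerulonephritis membranous,
Renal and urinary disorders,Nephropathies,glomerulonephritis and nephrotic syndrome,Glomerulonephritis minimal lesion,
Renal and urinary disorders,Nephropathies,glomerulonephritis and nephrotic syndrome,Nephritic syndrome,
Renal and urinary disorders,Nephropathies,nephritis NEC,Nephritis,
Renal and urinary disorders,Nephropathies,nephritis NEC,Tubulointerstitial nephritis,
Renal and urinary disorders,Nephropathies,nephritis NEC,Nephritis allergic,
Renal and urinary disorders,Nephropathies,nephropathies and tubular disorders NEC,Nephropathy,
Renal and urinary disorders,Nephropathies,nephropathies and tubular disorders NEC,Nephropathy toxic,
Renal and urinary disorders,Nephropathies,nephropathies and tubular disorders NEC,Renal tubular necrosis,
Renal and urinary disorders,Nephropathies,nephropathies and tubular disorders NEC,Renal tubular disorder,
Renal and urinary disorders,Nephropathies,nephropathies and tubular disorders NEC,Fanconi syndrome acquired,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal disorders NEC,Renal disorder,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal disorders NEC,Renal injury,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal disorders NEC,Fluid retention,
Renal and urinary disorders,Renal disorders (excl nephropathies),renal disorders NEC,Renal atrophy,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal hypertension and related conditions,Renal hypertension,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal hypertension and related conditions,Hypertensive nephropathy,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal vascular and ischaemic conditions,Thrombotic microangiopathy,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal vascular and ischaemic conditions,Haemolytic uraemic syndrome,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal vascular and ischaemic conditions,Renal artery thrombosis,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal vascular and ischaemic conditions,Renal infarct,
Renal and urinary disorders,Renal vascular and hypertensive conditions,renal vascular and ischaemic conditions,Renal vein thrombosis,
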
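# pepmeta

Read, modify, and validate **Portable Encapsulated Projects (PEPs)** — the
plain-text standard for organizing biological sample metadata — in R.

## The problem

Sample-intensive projects (RNA-seq, ATAC-seq, methylation panels, ...) all
need the same thing: a table of samples, each row pointing at data files,
plus a handful of project-level settings. In practice every pipeline invents
its own sheet format, so moving one dataset between two tools, or one
project between two compute environments, means rewriting metadata by hand.
The PEP format fixes this with two small files:

- a **YAML configuration file** holding project-level attributes, and
- a **CSV sample table** (one header row of attribute names, one data row
  per sample), optionally joined by a **subsample table** whose repeated
  rows become multi-valued attributes (e.g. several FASTQ files per
  sample).

Portability comes from *modifiers* declared in the config, never in the
CSV:

| kind | name | effect |
|------|------|--------|
| project | `import` | merge another config; nearest definition of each top-level key wins |
| project | `amend` | embed named config variants, activated at load time |
| sample | `remove` | delete an attribute from all samples |
| sample | `append` | add a constant attribute to all samples |
| sample | `duplicate` | copy an attribute under a new name |
| sample | `imply` | set attributes conditionally on existing values |
| sample | `derive` | rewrite source keys through string templates such as `"$DATAPATH/{sample_name}.fastq.gz"` |

Sample modifiers apply in the fixed order remove → append → duplicate →
imply → derive, so derived templates can reference appended or implied
attributes. A processed project can then be checked by a **two-stage
validator**: stage 1 validates the resolved config, stage 2 validates each
*processed* sample against a JSON-Schema-style document extended with
`imports` (a project must satisfy every imported schema) and
`required_files` (attributes whose values must be paths to existing
files).

The package is for anyone building or consuming sample sheets: pipeline
authors who want to declare their input requirements as a schema, and
analysts who want one metadata description to work across tools and
machines.

## Worked example

`project_config.yaml`:

```yaml
sample_table: samples.csv
sample_modifiers:
  append:
    genome: hg38
  imply:
    - if:
        organism: human
      then:
        macs_genome: hs
  derive:
    attributes: [read1]
    sources:
      local: "$DATAPATH/{sample_name}.fastq.gz"
```

`samples.csv`:

```
sample_name,organism,read1
frog_1,frog,local
human_1,human,local
```

```r
library(pepmeta)
prj <- load_project("project_config.yaml",
                    env = list(DATAPATH = "/project/data"))
sample_table(prj)
```

```
  sample_name organism                          read1 genome macs_genome
1      frog_1     frog  /project/data/frog_1.fastq.gz   hg38        <NA>
2     human_1    human /project/data/human_1.fastq.gz   hg38          hs
```

Every sample gained the constant `genome` (append); only the human sample
gained `macs_genome` (imply, condition not met for the frog); and the
`read1` source key `local` was rewritten by its template, with
`$DATAPATH` taken from the supplied environment (derive). The CSV itself
never changed — pointing the same project at another machine only requires
a different `DATAPATH`.

Validation and the command-line interface:

```r
validate_pep(prj, load_schema("pipeline_schema.yaml"))
```

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pep.R", package="pepmeta"))')" \
    validate -s pipeline_schema.yaml project_config.yaml   # exit 0 iff valid
pep.R inspect project_config.yaml
pep.R convert --format json project_config.yaml            # processed samples
```

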
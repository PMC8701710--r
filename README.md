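# medsql

Natural-language questions about electronic medical records — *"tell me the
insurance and primary disease of james sloan"* — answered by executable SQL
over a five-table EMR-style relational schema. `medsql` is an R
implementation of a grammar-constrained neural text-to-SQL generator for
clinicians' questions, together with everything needed to train and evaluate
it end to end on one CPU: a schema linker, a self-attention encoder, a
constrained LSTM decoder with pointer networks, execution-based metrics, and
a synthetic template-based corpus generator (no clinical data required or
included).

## The model

Rather than emitting SQL as a word sequence, the decoder derives a syntax
tree under a fixed 24-production grammar

```
Z -> R
R -> Select | Select Filter
Select -> A | A A | A A A
A -> agg C T            agg ∈ {none, max, min, count, sum, avg, count(distinct)}
Filter -> and Filter Filter | or Filter Filter
Filter -> op A V         op ∈ {=, !=, >, >=, <, <=, like, not like}
Filter -> between A V V
```

serialized depth-first into four action types: **ApplyRule** (expand a
nonterminal), **SelectColumn** (a memory-enhanced pointer over schema
columns), **SelectTable** (pruned to tables containing the chosen column),
and **SelectValue** (start/end pointers copying a question span). Question
n-grams matching column/table names are marked during schema linking and
encoded jointly with the schema; decoding is masked to grammar-admissible
actions at every step, so every output parses and renders to valid SQL.
Extracted condition values are snapped to database content by ROUGE-L
(LCS-based F1). Predictions are scored by logic-form accuracy
(`Acc_LF`, canonical token equality), execution accuracy (`Acc_EX`, equal
result tables on a populated SQLite fixture), and a five-component
breakdown (aggregation operation/column, table, condition column+operator,
condition value).

## Worked example

```r
library(medsql)

schema  <- make_schema()                          # demographic/diagnoses/procedures/prescriptions/lab
records <- sample_records(schema, n_patients = 300, seed = 1001)
gen     <- generate_pairs(schema, records,
                          gen_config(n_pairs = 3000, n_patients = 300, seed = 1001))

vocab <- build_vocab(Filter(function(e) e$split == "train", gen$examples), schema)
model <- medsql_model(vocab, schema,
                      model_config(enc_dim = 32, enc_layers = 1,
                                   enc_heads = 2, dec_dim = 64), seed = 1)
ckpt  <- train_model(gen$examples, model,
                     train_config(lr = 2e-3, epochs = 12, lr_decay = 0.85,
                                  seed = 1), schema)
#> epoch 1  loss 7.3056  val Acc_LF 0.645
#> epoch 2  loss 0.8330  val Acc_LF 0.840
#> epoch 3  loss 0.3910  val Acc_LF 0.925
#> ...
#> epoch 12  loss 0.0853  val Acc_LF 0.935

test_ex <- Filter(function(e) e$split == "test", gen$examples)
preds   <- predict_sql(vapply(test_ex, `[[`, character(1), "question"),
                       ckpt$model, schema, gen$db)
golds   <- vapply(test_ex, `[[`, character(1), "sql")
acc_lf(preds, golds)$acc           #> 0.9633333
acc_ex(preds, golds, gen$db)$acc   #> 0.9633333
```

A held-out question such as *"what is the short title of diagnoses for
patient elizabeth lewis?"* decodes to

```sql
select diagnoses."short_title" from diagnoses
  inner join demographic on diagnoses.hadm_id = demographic.hadm_id
  where demographic."name" = "elizabeth lewis"
```

`Acc_LF = 0.963` means 96% of held-out predictions match the gold query
token-for-token after canonicalization; `Acc_EX` counts predictions whose
execution result equals the gold result (column order respected, row order
not), and can only be at or above `Acc_LF`.

The package also bundles five gold/predicted pairs that illustrate how the
two metrics diverge (join order, select-column order, wrong value, wrong
column, flipped operator) with a fixture built so the last three return
different results:

```r
db <- case_study_fixture()
cs <- case_study_pairs()
evaluate_pairs(cs$pred, cs$gold, db)
#> <medsql_report> n=5  Acc_LF=0.000  Acc_EX=0.200
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/medsql`:

```sh
medsql generate --n 1000 --patients 200 --seed 7 --out data/
medsql train    --corpus data/corpus.jsonl --schema data/schema.yaml --out model.rds
medsql predict  --ckpt model.rds --questions q.txt --db data/fixture.sqlite --out pred.txt
medsql evaluate --pred pred.txt --gold gold.txt --db data/fixture.sqlite --out report.json
```

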